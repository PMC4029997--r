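target,fn_min,fn_max
1kviA,0.44,0.55
1pgx,0.31,0.42
1cy5A,0.50,0.62
1shfA,0.32,0.59
1r69,0.52,0.63
1csp,0.43,0.55
1ah9,0.37,0.57
1b72A,0.29,0.49
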