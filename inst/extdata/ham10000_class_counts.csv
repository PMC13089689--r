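class,count
akiec,327
bcc,514
bkl,1099
df,115
mel,1113
nv,6705
vasc,142
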