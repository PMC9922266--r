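input: /tmp/RtmppYSufl/file55d7f57e116/g.fasta
out_dir: '.'
motif_len: 3
min_rc: 4
scheme: cnt
q: 0.1
ks:
- 5
- 10
- 15
- 20
- 23
holdout_fraction: 0.15
sample_threshold: 0.1666667
feature_scheme: zsc
svm_c: 0.1
svm_gamma: 0.1
svm_kernel: linear
grid_search: no
folds: 3
zero_fill: no
leakage_safe: no
n_genes: 60
gene_length: 600
seed: 1
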