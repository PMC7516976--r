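# Empirical quantiles of sup_{0<=s<=1} ||B_d(s)||^2 for a
# d-dimensional standard Brownian bridge.
# Generated with dpdcusum::simulate_bb_sup:
#   set.seed(20200424); simulate_bb_sup(dim, grid_size = 2000,
#                                       reps = 200000) for dim = 1..6
# Regenerate via the CLI: dpdcusum.R critvals --dim <d> --reps 200000 --grid 2000
dim,level,value
1,0.1,1.4643
1,0.05,1.801
1,0.01,2.5999
2,0.1,2.0707
2,0.05,2.462
2,0.01,3.3612
3,0.1,2.5825
3,0.05,3.0085
3,0.01,3.9294
4,0.1,3.0388
4,0.05,3.4967
4,0.01,4.4935
5,0.1,3.4677
5,0.05,3.9404
5,0.01,4.9875
6,0.1,3.8688
6,0.05,4.3652
6,0.01,5.4426
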