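# scaled-down noise-free study case 1: non-adjacent bad detector bins with
# angle-constant offsets, reconstructed with the l0-smth-ring algorithm
case = 1
n = 128
seed = 1
b0 = 1e6
norm = l0
rho = 4
delta = 0.5
beta_prime = 0.05
eta = 0.01
K = 300
L = 2
constrained = FALSE
# nonconvex l0 update needs a warm start (see the methods vignette)
init = fbp
out_dir = paper_case1_small_out
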