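# SYNTHETIC pair-coefficient table for bidisperse hard-sphere short-time
# self-diffusion (version 1).  NOT the published Stokesian-dynamics
# polynomials: a stand-in constructed to honour the known limits.
#   pair_t/pair_r: first-order pairwise coefficient alpha(lambda) for the
#     translational / rotational normalized diffusivity, lambda = crowder
#     radius / tracer radius.  Constructed as
#       alpha_t(lambda) = -1.2 - 1.3 * 0.4858^lambda
#       alpha_r(lambda) = -2.5 * 0.2524^lambda
#     pinned to the monodisperse virial values alpha_t(1) = -1.8315,
#     alpha_r(1) = -0.631 and the effective-medium (Einstein viscosity)
#     limit alpha -> -2.5 as lambda -> 0; |alpha| decreases for larger
#     crowders, which reproduces the small-faster / large-slower ordering.
#   quad_t/quad_r: composition-independent quadratic terms, the
#     monodisperse second-order virial coefficients (+0.88, -0.726).
#   phi_max: fitted range of the polynomials in total volume fraction.
term,lambda,value
pair_t,0.1,-2.409453
pair_t,0.15,-2.366573
pair_t,0.2,-2.325213
pair_t,0.3,-2.246841
pair_t,0.4,-2.173927
pair_t,0.5,-2.106092
pair_t,0.7,-1.984266
pair_t,1,-1.8315
pair_t,1.4,-1.673134
pair_t,2,-1.506802
pair_t,3,-1.349044
pair_t,5,-1.235175
pair_t,7,-1.208301
pair_t,10,-1.200952
pair_r,0.1,-2.178457
pair_r,0.15,-2.033543
pair_r,0.2,-1.898270
pair_r,0.3,-1.654119
pair_r,0.4,-1.441371
pair_r,0.5,-1.255986
pair_r,0.7,-0.953680
pair_r,1,-0.631
pair_r,1.4,-0.363802
pair_r,2,-0.159264
pair_r,3,-0.040198
pair_r,5,-0.002561
pair_r,7,-0.000163
pair_r,10,-0.000003
quad_t,,0.88
quad_r,,-0.726
phi_max,,0.63
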