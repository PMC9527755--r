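# Bound-atom incoherent neutron scattering cross sections, barn.
# Source: V. F. Sears, Neutron News 3(3), 26-37 (1992), natural abundance
# unless an isotope is named (D = 2H). Version 1.
element,sigma_inc_barn
H,80.26
D,2.05
C,0.001
N,0.50
O,0.0008
Na,1.62
Mg,0.08
P,0.005
S,0.007
Cl,5.3
K,0.27
Ca,0.05
Fe,0.40
Zn,0.077
Se,0.32
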