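# stopped-flow FRET kinetic fit parameters for QD-DiMan binding the labelled lectins
# association: y(t) = y_max (1 - exp(-k_on x0 t)) - a t, x0 = 20 nM
# dissociation (excess mannose competition): y(t) = y_eq + (y_0 - y_eq) exp(-k_off' t) - a t
# k_on in 1e7 /M/s; drift constants a in 1e-3 /s
lectin,assoc_y_max,assoc_k_on_1e7,assoc_a_1e3,dissoc_y_0,dissoc_y_eq,dissoc_k_off_prime,dissoc_a_1e3
DC-SIGN,2.49,2.24,10.3,1.261,0.129,3.23,1.57
DC-SIGN-C,2.59,2.92,5.1,1.722,0.131,2.95,0.93
DC-SIGNR,0.0532,16,-2.5,0.067,0.042,0.45,0.02
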