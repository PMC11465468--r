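{"schema_version":"1","delta_e_ev":27.5083374635166,"lambda_c":-0.394844359444302,"n_exc":1.00000000000002,"pct_t1":99.9999999999979,"pct_t2":2.1094237467878e-12,"method":"coox","functional":"hf","basis":"sto-3g","spin_type":"singlet_restricted","scaled_used":false,"residual":6.43929354282591e-15,"commutator_norm":5.55111512312578e-17,"macro_iterations":2,"micro_iterations":38,"converged":true,"collapsed":false}
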