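patient_id,volume_cm3,counts,A_rs_MBq,dose_factor_mGy_MBq,self_dose_Gy,nuclide
13_11_23_177Lu,342.5,818,286,40.7,11.6,Lu177
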