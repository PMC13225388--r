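patient_id,volume_cm3,mean_concentration_Bq_ml,A_rs_MBq,dose_factor_mGy_MBq,self_dose_mGy,delta_p_nor,delta_R_t_uSv_h,nuclide,reinjected
04_05_18F_07,25.7,88286,3.3,16.5,54.8,0.15,803,F18,TRUE
17_07_23_18F_05,10.1,111222,1.6,40.1,65.9,0.26,276,F18,FALSE
05_09_23_18F_02,52.9,56897,4.4,8.4,37,0.47,70,F18,FALSE
06_09_23_18F_05,36.2,941451,49.9,6.84,341.4,0.12,2432,F18,TRUE
25_10_23_18F_10,4.3,387552,2.4,90.8,221.6,0.45,229,F18,FALSE
26_10_23_18F_10,13.3,623173,12.1,30.9,375,0.22,1571,F18,FALSE
15_11_23_18F_04,24.8,616698,22.4,17,381,0.08,13473,F18,TRUE
22_09_18F_04,14.9,856960,18.7,27.6,517,0.1,667,F18,TRUE
03_10_18F_06,15.4,430253,9.7,26.8,261,0.32,578,F18,FALSE
07_10_18F_04,24.9,249525,9.1,17,155,0.28,272,F18,FALSE
15_03_18F_10,14.9,450383,9.8,27.7,272,0.08,4346,F18,TRUE
17_01_68Ga_02,16.3,296721,7.1,41.1,291,0.32,485,Ga68,FALSE
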