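# Nuclide physical data and sediment distribution coefficients (Kd, L/kg dry).
# Half-lives: Co-60 5.27 y; Cs-137 30.1 y; Sr-90 28.8 y.
# Kd geometric means are generic IAEA-handbook sediment screening values
# ("expected value" variant); kd_gsd is the lognormal geometric standard
# deviation applied when Kd is sampled stochastically (freshwater runs),
# a calibration input of the package (see the methods vignette).
name,half_life_y,kd_fresh_gm_L_per_kg,kd_marine_gm_L_per_kg,kd_gsd,source_note
Co-60,5.27,5000,300000,2.5,generic freshwater / coastal sediment Kd expected values
Cs-137,30.1,10000,3000,2.5,freshwater upper-range sediment Kd consistent with reservoir response; marine expected value
Sr-90,28.8,1000,8,2.5,freshwater sediment Kd expected value; oceanic (low-sorption) marine Kd
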