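# Reported environmental monitoring ranges, coastal bottom sediments
# (Bq/kg dry); sampling-point locations were not published, so the ranges
# apply to every modelled receptor.
nuclide,receptor,lo,hi,below_detection
Co-60,,0.3,1.1,FALSE
Cs-137,,0.7,10,FALSE
Sr-90,,1,3,FALSE
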