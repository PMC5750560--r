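# Reported environmental monitoring ranges, reservoir bottom sediments
# (Bq/kg dry). Sr-90 was always below the detection limit; its lo/hi are a
# nominal detection-limit placeholder, flagged below_detection.
nuclide,receptor,lo,hi,below_detection
Co-60,,12,40,FALSE
Cs-137,,11,112,FALSE
Sr-90,,1,1,TRUE
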