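# Internal functions exercised directly by the tests.
write_tiff <- ctfish:::write_tiff
read_tiff <- ctfish:::read_tiff
derive_seed <- ctfish:::derive_seed
cpp_gaussian_blur <- ctfish:::cpp_gaussian_blur
cpp_edt <- ctfish:::cpp_edt
cpp_dilate26 <- ctfish:::cpp_dilate26
cpp_label_components <- ctfish:::cpp_label_components
cpp_hysteresis <- ctfish:::cpp_hysteresis
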