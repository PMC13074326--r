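chromosome	n_insertion	n_deletion
Chr01	7498	13648
Chr02	8052	13766
Chr03	12137	14721
Chr04	11579	15166
Chr05	11378	14644
Chr06	7865	12458
Chr07	11313	14316
Chr08	10758	14980
Chr09	12544	14534
Chr10	10925	13165
Chr11	8542	11011
Chr12	9342	11454
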