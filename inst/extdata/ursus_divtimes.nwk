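(americanus:5.0,(spelaeus:2.8,(arctos:1.6,maritimus:1.6):1.2):2.2);
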