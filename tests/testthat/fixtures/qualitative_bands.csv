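lo,hi,label
62,89,No to low interference
91,105,Mild interference
106,117,Moderate interference
118,133,Substantial interference
135,154,Severe interference
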