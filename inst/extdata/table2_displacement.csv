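axis,invitro_span,insilico_span
x,0.795,0.821
y,0.53,0.561
z,0.067,0.0749
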