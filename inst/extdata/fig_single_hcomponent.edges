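# root: C0
C0 C1
C1 C2
C2 C3
C3 C0
C2 C4
C4 C5
C5 C0
C4 C6
C6 C1
C7 C8
C8 C2
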