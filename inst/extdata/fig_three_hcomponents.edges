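# root: C0
C0 C1
C1 C2
C1 C4
C1 C6
C2 C3
C3 C2
C4 C5
C5 C4
C6 C7
C7 C6
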