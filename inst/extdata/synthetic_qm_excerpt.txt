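Synthetic excerpt of an excited-state output block (hand-crafted fixture).

-----------------------------------------------------------------------
EXCITED STATES SUMMARY
-----------------------------------------------------------------------
STATE 1: E= 2.7546 eV, 450.0 nm  f= 1.200
STATE 2: E= 3.7571 eV, 330.0 nm  f= 0.050
-----------------------------------------------------------------------
Total run time: 0 days 0 hours
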