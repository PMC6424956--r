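# Synthetic (illustrative) residue-formula table for non-natural residues.
# These formulas are plausible stand-ins used in examples and tests; supply
# measured formulas for real analyses. Columns: code, formula (Hill).
code,formula
B,C10H17NO
J,C10H10N2O2
O,C9H8FNO
U,C6H9NO
Z,C6H6N2OS
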