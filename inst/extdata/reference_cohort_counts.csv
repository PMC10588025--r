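stratum,n_total,n_diabetic
all,914652,91505
female,510873,58023
male,403779,33482
Young,355925,6750
Middle-Aged,203166,14092
Old,355561,70663
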