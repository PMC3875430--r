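# Example flowering-gene annotation list for the local annotation join.
# Keyword patterns match transcript descriptions (case-insensitive);
# id rows match transcript identifiers exactly. The id entries are
# synthetic examples for the packaged fixtures.
type	value
keyword	flower
keyword	heading date
keyword	photoperiod
keyword	florigen
keyword	circadian
keyword	vernalization
keyword	gibberellin
id	synT-FT1
id	synT-SPL9
id	synT-AP2
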