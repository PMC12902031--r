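patient	variant	short_stature	microcephaly	developmental_delay	language_delay	motor_delay	intellectual_disability	seizures	hypotonia	dysmorphic_features	palatal_abnormality	hand_foot_abnormalities	gastrointestinal_abnormalities	cardiac_abnormalities	feeding_difficulties	short_attention
P01	pLoF	absent	present	mild	present	mild	absent	present	absent	mild	absent	absent	mild	mild	absent	absent
P02	missense	mild	unknown	absent	absent	absent	mild	absent	absent	present	mild	absent	mild	mild	mild	absent
P03	missense	absent	absent	mild	absent	absent	mild	absent	absent	present	unknown	absent	present	present	unknown	present
P04	missense	mild	present	mild	absent	absent	unknown	mild	mild	mild	mild	mild	absent	mild	present	mild
P05	missense	present	present	present	mild	present	absent	present	absent	present	present	mild	absent	mild	absent	present
P06	missense	mild	present	absent	mild	absent	unknown	present	present	present	absent	unknown	mild	absent	unknown	absent
P07	missense	absent	absent	absent	absent	absent	absent	absent	present	absent	absent	absent	absent	present	present	present
P08	missense	present	absent	mild	present	present	present	mild	mild	present	present	mild	present	present	absent	present
P09	missense	mild	absent	present	mild	mild	absent	present	absent	mild	absent	present	present	present	unknown	unknown
P10	pLoF	absent	mild	absent	absent	absent	unknown	absent	mild	absent	absent	absent	absent	mild	absent	absent
P11	missense	absent	absent	absent	present	present	present	absent	absent	absent	mild	absent	unknown	present	absent	present
P12	missense	absent	unknown	absent	mild	present	unknown	present	unknown	absent	present	absent	present	present	absent	mild
P13	missense	present	absent	present	present	present	present	absent	mild	mild	unknown	absent	unknown	unknown	mild	absent
P14	missense	absent	absent	mild	absent	mild	unknown	mild	absent	present	present	present	present	mild	present	mild
P15	pLoF	absent	unknown	mild	present	absent	mild	absent	present	absent	unknown	absent	absent	absent	mild	absent
P16	pLoF	absent	absent	mild	mild	absent	unknown	mild	absent	absent	mild	absent	absent	mild	unknown	absent
P17	pLoF	present	absent	absent	absent	present	mild	present	absent	absent	unknown	absent	absent	absent	mild	absent
P18	pLoF	absent	absent	mild	mild	absent	unknown	absent	absent	mild	absent	mild	unknown	unknown	mild	absent
P19	missense	present	unknown	present	absent	present	unknown	present	unknown	present	mild	present	absent	absent	present	absent
P20	missense	present	present	absent	absent	absent	mild	present	mild	present	mild	absent	present	absent	absent	absent
P21	pLoF	absent	absent	absent	absent	absent	unknown	absent	absent	absent	absent	absent	mild	absent	unknown	mild
P22	missense	present	unknown	mild	present	mild	unknown	present	absent	unknown	unknown	present	mild	present	unknown	present
P23	pLoF	mild	absent	present	absent	mild	unknown	absent	absent	mild	absent	absent	mild	absent	absent	absent
P24	missense	absent	mild	absent	absent	present	absent	present	absent	mild	absent	present	mild	present	mild	absent
P25	missense	present	present	absent	absent	mild	unknown	absent	absent	mild	present	present	present	absent	unknown	absent
P26	pLoF	absent	absent	absent	absent	absent	absent	absent	mild	absent	absent	absent	mild	mild	present	present
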