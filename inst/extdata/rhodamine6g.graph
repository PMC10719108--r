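# Connectivity of the rhodamine-6G cation
# (9-[2-(ethoxycarbonyl)phenyl]-3,6-bis(ethylamino)-2,7-dimethylxanthylium)
# with its chloride counter-ion.  Composition C28 H31 N2 O3 Cl.
# Records: atom <label> <element> [ar] / bond <label1> <label2> [ar]
#
# Xanthene tricycle: outer rings CA1-CA6 and CB1-CB6 (aromatic), bridged by
# the meso carbon C9 and ring oxygen O13.
atom CA1 C ar
atom CA2 C ar
atom CA3 C ar
atom CA4 C ar
atom CA5 C ar
atom CA6 C ar
atom CB1 C ar
atom CB2 C ar
atom CB3 C ar
atom CB4 C ar
atom CB5 C ar
atom CB6 C ar
atom C9 C ar
atom O13 O
bond CA1 CA2 ar
bond CA2 CA3 ar
bond CA3 CA4 ar
bond CA4 CA5 ar
bond CA5 CA6 ar
bond CA6 CA1 ar
bond CB1 CB2 ar
bond CB2 CB3 ar
bond CB3 CB4 ar
bond CB4 CB5 ar
bond CB5 CB6 ar
bond CB6 CB1 ar
bond C9 CA1
bond C9 CB1
bond O13 CA6
bond O13 CB6
# aromatic hydrogens on the xanthene rings
atom HA2 H
atom HA5 H
atom HB2 H
atom HB5 H
bond HA2 CA2
bond HA5 CA5
bond HB2 CB2
bond HB5 CB5
# ring methyls (2,7-dimethyl)
atom CM1 C
atom HM1a H
atom HM1b H
atom HM1c H
atom CM2 C
atom HM2a H
atom HM2b H
atom HM2c H
bond CM1 CA3
bond HM1a CM1
bond HM1b CM1
bond HM1c CM1
bond CM2 CB3
bond HM2a CM2
bond HM2b CM2
bond HM2c CM2
# ethylamino groups (3,6-bis(ethylamino)); N-H are the amide-class hydrogens
atom N15 N
atom H15 H
atom CE1 C
atom HE1a H
atom HE1b H
atom CE2 C
atom HE2a H
atom HE2b H
atom HE2c H
bond N15 CA4
bond H15 N15
bond CE1 N15
bond HE1a CE1
bond HE1b CE1
bond CE2 CE1
bond HE2a CE2
bond HE2b CE2
bond HE2c CE2
atom N16 N
atom H16 H
atom CE3 C
atom HE3a H
atom HE3b H
atom CE4 C
atom HE4a H
atom HE4b H
atom HE4c H
bond N16 CB4
bond H16 N16
bond CE3 N16
bond HE3a CE3
bond HE3b CE3
bond CE4 CE3
bond HE4a CE4
bond HE4b CE4
bond HE4c CE4
# 2-(ethoxycarbonyl)phenyl arm on the meso carbon
atom P1 C ar
atom P2 C ar
atom P3 C ar
atom P4 C ar
atom P5 C ar
atom P6 C ar
atom HP3 H
atom HP4 H
atom HP5 H
atom HP6 H
bond P1 P2 ar
bond P2 P3 ar
bond P3 P4 ar
bond P4 P5 ar
bond P5 P6 ar
bond P6 P1 ar
bond P1 C9
bond HP3 P3
bond HP4 P4
bond HP5 P5
bond HP6 P6
atom C21 C
atom O22 O
atom O31 O
atom C32 C
atom H32a H
atom H32b H
atom C33 C
atom H33a H
atom H33b H
atom H33c H
bond C21 P2
bond O22 C21
bond O31 C21
bond C32 O31
bond H32a C32
bond H32b C32
bond C33 C32
bond H33a C33
bond H33b C33
bond H33c C33
# chloride counter-ion (separate component)
atom CL1 Cl
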