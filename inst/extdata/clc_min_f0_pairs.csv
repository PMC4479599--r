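subject,treatment,control_hz,treatment_hz,published_delta_hz
Bart,A,1511,1564,53
Bart,B,1393,1507,114
Bart,C,1423,1499,77
Bart,D,1553,1497,-57
Bart,E,1568,1557,-11
Bart,F,1478,1409,-69
Jerry,A,1579,2508,929
Jerry,B,1488,1496,9
Jerry,C,1536,1505,-30
Jerry,D,1653,1418,-236
Jerry,E,1489,1444,-45
Jerry,F,1693,1545,-148
Mulva,A,1653,1761,107
Mulva,B,1716,1656,-59
Mulva,C,1564,1631,67
Mulva,D,1674,1618,-56
Mulva,E,1671,1597,-74
Mulva,F,1649,1659,11
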