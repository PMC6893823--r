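O=C1CCC(O1)Cc1cc(O)c(c(c1)O)O	M001
O=C1CCC(O1)Cc1ccc(c(c1)O)O	M002
O=C1CCC(O1)Cc1cc(O)cc(c1)O	M003
O=C1CCC(O1)Cc1cccc(c1)O	M004
O=C1CCC(O1)Cc1ccc(cc1)O	M005
O=C1CCC(O1)Cc1cc(O)c(c(c1)OS(=O)(=O)O)O	M006
O=C1CCC(O1)Cc1cc(O)c(c(c1)O)OS(=O)(=O)O	M007
COc1c(O)cc(cc1OS(=O)(=O)O)CC1CCC(=O)O1	M008
O=C1CCC(O1)Cc1ccc(c(c1)O)OS(=O)(=O)O	M009
COc1cc(CC2CCC(=O)O2)cc(c1OS(=O)(=O)O)O	M010
O=C1CCC(O1)Cc1cc(O)cc(c1)OS(=O)(=O)O	M011
COc1cc(CC2CCC(=O)O2)cc(c1O)OS(=O)(=O)O	M012
O=C1CCC(O1)Cc1ccc(c(c1)OS(=O)(=O)O)O	M013
COc1cc(ccc1OS(=O)(=O)O)CC1CCC(=O)O1	M014
O=C1CCC(O1)Cc1cccc(c1)OS(=O)(=O)O	M015
COc1ccc(cc1OS(=O)(=O)O)CC1CCC(=O)O1	M016
O=C1CCC(O1)Cc1ccc(cc1)OS(=O)(=O)O	M017
O=C1CCC(O1)Cc1cc(OC2OC(C(=O)O)C(C(C2O)O)O)c(c(c1)O)O	M018
O=C1CCC(O1)Cc1cc(O)c(c(c1)O)OC1OC(C(=O)O)C(C(C1O)O)O	M019
O=C1CCC(O1)Cc1ccc(c(c1)O)OC1OC(C(=O)O)C(C(C1O)O)O	M020
COc1cc(CC2CCC(=O)O2)cc(c1OC1OC(C(=O)O)C(C(C1O)O)O)O	M021
COc1c(OC2OC(C(=O)O)C(C(C2O)O)O)cc(cc1O)CC1CCC(=O)O1	M022
O=C1CCC(O1)Cc1cc(OC2OC(C(=O)O)C(C(C2O)O)O)cc(c1)O	M023
O=C1CCC(O1)Cc1ccc(c(c1)OC1OC(C(=O)O)C(C(C1O)O)O)O	M024
COc1cc(CC2CCC(=O)O2)cc(c1O)OC1OC(C(=O)O)C(C(C1O)O)O	M025
O=C1CCC(O1)Cc1cccc(c1)OC1OC(C(=O)O)C(C(C1O)O)O	M026
COc1ccc(cc1OC1OC(C(=O)O)C(C(C1O)O)O)CC1CCC(=O)O1	M027
COc1cc(ccc1OC1OC(C(=O)O)C(C(C1O)O)O)CC1CCC(=O)O1	M028
O=C1CCC(O1)Cc1ccc(cc1)OC1OC(C(=O)O)C(C(C1O)O)O	M029
O=C1CCC(O1)Cc1cc(O)c(c(c1)OS(=O)(=O)O)OC1OC(C(=O)O)C(C(C1O)O)O	M030
O=C1CCC(O1)Cc1cc(OC2OC(C(=O)O)C(C(C2O)O)O)c(c(c1)O)OS(=O)(=O)O	M031
O=C1CCC(O1)Cc1cc(OC2OC(C(=O)O)C(C(C2O)O)O)c(c(c1)OS(=O)(=O)O)O	M032
COc1c(OC2OC(C(=O)O)C(C(C2O)O)O)cc(cc1OS(=O)(=O)O)CC1CCC(=O)O1	M033
O=C1CCC(O1)Cc1ccc(c(c1)OC1OC(C(=O)O)C(C(C1O)O)O)OS(=O)(=O)O	M034
COc1cc(CC2CCC(=O)O2)cc(c1OS(=O)(=O)O)OC1OC(C(=O)O)C(C(C1O)O)O	M035
O=C1CCC(O1)Cc1cc(OC2OC(C(=O)O)C(C(C2O)O)O)cc(c1)OS(=O)(=O)O	M036
COc1cc(CC2CCC(=O)O2)cc(c1OC1OC(C(=O)O)C(C(C1O)O)O)OS(=O)(=O)O	M037
O=C1CCC(O1)Cc1ccc(c(c1)OS(=O)(=O)O)OC1OC(C(=O)O)C(C(C1O)O)O	M038
O=C1CCC(O1)Cc1cc(O)c(c(c1)OS(=O)(=O)O)OS(=O)(=O)O	M039
O=C1CCC(O1)Cc1cc(OS(=O)(=O)O)c(c(c1)OS(=O)(=O)O)O	M040
COc1cc(CC2CCC(=O)O2)cc(c1OS(=O)(=O)O)OS(=O)(=O)O	M041
COc1c(cc(cc1OS(=O)(=O)O)CC1CCC(=O)O1)OS(=O)(=O)O	M042
O=C1CCC(O1)Cc1ccc(c(c1)OS(=O)(=O)O)OS(=O)(=O)O	M043
O=C1CCC(O1)Cc1cc(cc(c1)OS(=O)(=O)O)OS(=O)(=O)O	M044
COc1cc(CC2CCC(=O)O2)cc(c1O)O	M045
COc1c(O)cc(cc1O)CC1CCC(=O)O1	M046
COc1ccc(cc1O)CC1CCC(=O)O1	M047
COc1cc(ccc1O)CC1CCC(=O)O1	M048
OC(Cc1ccc(c(c1)O)O)CCC(=O)O	M049
OC(Cc1cccc(c1)O)CCC(=O)O	M050
OC(Cc1ccc(cc1)O)CCC(=O)O	M051
OC(Cc1ccccc1)CCC(=O)O	M052
OC(=O)CCCCc1ccccc1	M053
OC(Cc1ccc(c(c1)O)OS(=O)(=O)O)CCC(=O)O	M054
OC(Cc1ccc(c(c1)OS(=O)(=O)O)O)CCC(=O)O	M055
COc1cc(ccc1OS(=O)(=O)O)CC(CCC(=O)O)O	M056
OC(Cc1cccc(c1)OS(=O)(=O)O)CCC(=O)O	M057
COc1ccc(cc1OS(=O)(=O)O)CC(CCC(=O)O)O	M058
OC(Cc1ccc(cc1)OS(=O)(=O)O)CCC(=O)O	M059
OC(=O)CCC(Cc1ccc(c(c1)O)OC1OC(C(=O)O)C(C(C1O)O)O)O	M060
OC(=O)CCC(Cc1ccc(c(c1)OC1OC(C(=O)O)C(C(C1O)O)O)O)O	M061
OC(=O)CCC(Cc1cccc(c1)OC1OC(C(=O)O)C(C(C1O)O)O)O	M062
COc1ccc(cc1OC1OC(C(=O)O)C(C(C1O)O)O)CC(CCC(=O)O)O	M063
COc1cc(ccc1OC1OC(C(=O)O)C(C(C1O)O)O)CC(CCC(=O)O)O	M064
OC(=O)CCC(Cc1ccc(cc1)OC1OC(C(=O)O)C(C(C1O)O)O)O	M065
OC(=O)CCC(Cc1ccc(c(c1)OC1OC(C(=O)O)C(C(C1O)O)O)OS(=O)(=O)O)O	M066
OC(=O)CCC(Cc1ccc(c(c1)OS(=O)(=O)O)OC1OC(C(=O)O)C(C(C1O)O)O)O	M067
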