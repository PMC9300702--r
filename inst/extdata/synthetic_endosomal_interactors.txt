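EN001
EN002
EN003
EN004
EN005
EN006
EN007
EN008
EN009
EN010
EN011
EN012
EN013
EN014
EN015
EN016
EN017
EN018
EN019
EN020
EN021
EN022
EN023
EN024
EN025
EN026
EN027
EN028
EN029
EN030
EN031
EN032
EN033
EN034
EN035
EN036
EN037
EN038
EN039
EN040
EN041
EN042
EN043
EN044
EN045
EN046
EN047
EN048
EN049
EN050
EN051
EN052
EN053
SH001
SH002
SH003
SH004
SH005
SH006
SH007
SH008
SH009
SH010
SH011
SH012
SH013
SH014
SH015
SH016
SH017
SH018
SH019
SH020
SH021
SH022
SH023
SH024
SH025
SH026
SH027
SH028
SH029
SH030
SH031
SH032
SH033
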