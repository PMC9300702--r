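SH001
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
SU001
SU002
SU003
SU004
SU005
SU006
SU007
SU008
SU009
SU010
SU011
SU012
SU013
SU014
SU015
SU016
SU017
SU018
SU019
SU020
SU021
SU022
SU023
SU024
SU025
SU026
SU027
SU028
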