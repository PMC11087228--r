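"reaction_id","parameter","value","units"
"enzyme","enzyme.default_conc",0.01,"mM"
"init","init.TYR",0.5,"mM"
"sim","sim.horizon",24,"h"
"TAL","TAL.kcat",1e+05,"1/h"
"TAL","TAL.Km.TYR",0.5,"mM"
"C3H","C3H.k",54.62,"1/(mM*h)"
"COMT","COMT.kcat",15.19,"1/h"
"COMT","COMT.Km.CAA",0.305,"mM"
"FCS","FCS.kcat",23.14,"1/h"
"FCS","FCS.Km.CUA",0.68,"mM"
"FCS","FCS.Km.CAA",0.1634,"mM"
"FCS","FCS.Km.FEA",4.421,"mM"
"CCOAOMT","CCOAOMT.kcat",2.631,"1/h"
"CCOAOMT","CCOAOMT.Km.CACOA",0.04686,"mM"
"DCS","DCS.kcat",6.677,"1/h"
"DCS","DCS.Km.CUCOA",0.2346,"mM"
"DCS","DCS.Km.FECOA",0.6454,"mM"
"CURS","CURS.kcat.BDC",53.84,"1/h"
"CURS","CURS.kcat.DMC",1775,"1/h"
"CURS","CURS.kcat.CUR",155.1,"1/h"
"CURS","CURS.Km.CUCOA",0.01366,"mM"
"CURS","CURS.Km.DCUCOA",0.05398,"mM"
"CURS","CURS.Km.FECOA",0.2003,"mM"
"CURS","CURS.Km.DFECOA",0.465,"mM"
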