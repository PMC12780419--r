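child_id,visit_id,visit_date,text
c001,v001,2013-02-04,"Miserable overnight, pulling at right ear. R TM red and bulging. AOM, started amoxicillin."
c001,v002,2013-03-11,"Follow up. Ears examined, TM normal both sides. Afebrile, well."
c002,v003,2013-02-18,"Cough and coryza one week. Chest clear. Viral URTI, supportive care."
c002,v004,2013-05-02,"Knee pain after fall at kindy. ROM improving since physio. No swelling."
c003,v005,2013-01-21,"Mother reports brother has otitis media. Index child well today, immunisations given."
c003,v006,2013-06-30,""
c004,v007,2013-04-15,"Fever 38.5, irritable. L ear bulging drum, otitis media likely. Review 48h."
c004,v008,2013-07-09,"Rash on trunk, blanching. t/m pearly and intact. Likely viral exanthem."
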