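format-version: 1.2
ontology: mini-cardiac-phenotype

[Term]
id: CP:0000001
name: cardiovascular and laterality phenotype

[Term]
id: CP:0000002
name: abnormal left-right patterning
is_a: CP:0000001 ! cardiovascular and laterality phenotype

[Term]
id: CP:0000003
name: situs inversus totalis
is_a: CP:0000002 ! abnormal left-right patterning

[Term]
id: CP:0000004
name: heterotaxy
alt_id: CP:0000099
is_a: CP:0000002 ! abnormal left-right patterning

[Term]
id: CP:0000005
name: right atrial isomerism
is_a: CP:0000004 ! heterotaxy

[Term]
id: CP:0000006
name: left atrial isomerism
is_a: CP:0000004 ! heterotaxy

[Term]
id: CP:0000007
name: asplenia
is_a: CP:0000002 ! abnormal left-right patterning

[Term]
id: CP:0000008
name: dextrocardia
is_a: CP:0000002 ! abnormal left-right patterning

[Term]
id: CP:0000010
name: abnormal ventricular looping
is_a: CP:0000001 ! cardiovascular and laterality phenotype

[Term]
id: CP:0000011
name: L-looped ventricles
is_a: CP:0000010 ! abnormal ventricular looping

[Term]
id: CP:0000012
name: D-looped ventricles
is_a: CP:0000010 ! abnormal ventricular looping

[Term]
id: CP:0000015
name: abnormal great artery position
is_a: CP:0000001 ! cardiovascular and laterality phenotype

[Term]
id: CP:0000016
name: transposition of the great arteries
is_a: CP:0000015 ! abnormal great artery position

[Term]
id: CP:0000017
name: dextro-transposition of the great arteries
is_a: CP:0000016 ! transposition of the great arteries

[Term]
id: CP:0000018
name: levo-transposition of the great arteries
is_a: CP:0000016 ! transposition of the great arteries

[Term]
id: CP:0000019
name: malposition of the great arteries
is_a: CP:0000015 ! abnormal great artery position

[Term]
id: CP:0000020
name: D-malposition of the great arteries
is_a: CP:0000019 ! malposition of the great arteries

[Term]
id: CP:0000021
name: L-malposition of the great arteries
is_a: CP:0000019 ! malposition of the great arteries

[Term]
id: CP:0000022
name: congenitally corrected transposition of the great arteries
is_a: CP:0000018 ! levo-transposition of the great arteries
is_a: CP:0000026 ! discordant atrioventricular connection

[Term]
id: CP:0000025
name: abnormal atrioventricular connection
is_a: CP:0000001 ! cardiovascular and laterality phenotype

[Term]
id: CP:0000026
name: discordant atrioventricular connection
is_a: CP:0000025 ! abnormal atrioventricular connection

[Term]
id: CP:0000027
name: double inlet left ventricle
is_a: CP:0000025 ! abnormal atrioventricular connection

[Term]
id: CP:0000028
name: tricuspid atresia
is_a: CP:0000025 ! abnormal atrioventricular connection

[Term]
id: CP:0000029
name: mitral atresia
is_a: CP:0000025 ! abnormal atrioventricular connection

[Term]
id: CP:0000030
name: straddling atrioventricular valve
is_a: CP:0000025 ! abnormal atrioventricular connection

[Term]
id: CP:0000031
name: common atrioventricular canal
is_a: CP:0000025 ! abnormal atrioventricular connection

[Term]
id: CP:0000032
name: abnormal ventriculoarterial connection
is_a: CP:0000001 ! cardiovascular and laterality phenotype

[Term]
id: CP:0000033
name: double outlet right ventricle
is_a: CP:0000032 ! abnormal ventriculoarterial connection

[Term]
id: CP:0000035
name: right ventricular outflow tract obstruction
is_a: CP:0000001 ! cardiovascular and laterality phenotype

[Term]
id: CP:0000036
name: pulmonary stenosis
is_a: CP:0000035 ! right ventricular outflow tract obstruction

[Term]
id: CP:0000037
name: pulmonary atresia
is_a: CP:0000035 ! right ventricular outflow tract obstruction

[Term]
id: CP:0000040
name: septal defect
is_a: CP:0000001 ! cardiovascular and laterality phenotype

[Term]
id: CP:0000041
name: atrial septal defect
is_a: CP:0000040 ! septal defect

[Term]
id: CP:0000042
name: secundum atrial septal defect
is_a: CP:0000041 ! atrial septal defect

[Term]
id: CP:0000043
name: ventricular septal defect
is_a: CP:0000040 ! septal defect

[Term]
id: CP:0000045
name: single ventricle
is_a: CP:0000001 ! cardiovascular and laterality phenotype

[Term]
id: CP:0000047
name: abnormal aortic arch
is_a: CP:0000001 ! cardiovascular and laterality phenotype

[Term]
id: CP:0000048
name: coarctation of the aorta
is_a: CP:0000047 ! abnormal aortic arch

[Term]
id: CP:0000049
name: hypoplastic aortic arch
is_a: CP:0000047 ! abnormal aortic arch

[Term]
id: CP:0000050
name: subaortic stenosis
is_a: CP:0000001 ! cardiovascular and laterality phenotype

[Term]
id: CP:0000060
name: obsolete cardiac anomaly
is_obsolete: true

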