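smiles,expected_class,branch,note
CC,I_saturated,1,ethane
CCO,I_saturated,1,ethanol
CCN,I_saturated,1,ethylamine
C1CCCCC1,I_saturated,1,cyclohexane
OC1CCCCC1,I_saturated,1,cyclohexanol (reference trio)
COC,I_saturated,1,dimethyl ether
CC(C)C,I_saturated,1,isobutane
NCCO,I_saturated,1,ethanolamine
C1CCOC1,I_saturated,1,tetrahydrofuran
CNC,I_saturated,1,dimethylamine
OC1CCCC=C1,II_single_unsaturated,5,cyclohex-2-enol (reference trio)
C=C,II_single_unsaturated,5,ethene
CC#C,II_single_unsaturated,5,propyne
CC=O,II_single_unsaturated,5,acetaldehyde (lone carbonyl)
CC(C)=O,II_single_unsaturated,5,acetone
CC(N)=O,II_single_unsaturated,2,acetamide
CCC(=O)NC,II_single_unsaturated,2,N-methylpropanamide
CC(=O)O,II_single_unsaturated,2,acetic acid
CC(=O)OC,II_single_unsaturated,2,methyl acetate
NCC(=O)O,II_single_unsaturated,2,glycine
NC(C)C(=O)O,II_single_unsaturated,2,alanine
C=CC(N)=O,II_single_unsaturated,2,acrylamide (amide wins over polyunsaturation)
C=CC(=O)OC,II_single_unsaturated,2,methyl acrylate (ester wins over polyunsaturation)
C=CC=C,II_single_unsaturated,5,butadiene (polyunsaturated non-carbonyl)
CC=CC=CC,II_single_unsaturated,5,hexa-2-4-diene
C#CC#C,II_single_unsaturated,5,butadiyne
Oc1ccccc1,III_aromatic_carbonyl,3,phenol (reference trio)
c1ccccc1,III_aromatic_carbonyl,3,benzene
Cc1ccccc1,III_aromatic_carbonyl,3,toluene
c1ccncc1,III_aromatic_carbonyl,3,pyridine
c1ccoc1,III_aromatic_carbonyl,3,furan
O=Cc1ccccc1,III_aromatic_carbonyl,3,benzaldehyde
CC(=O)c1ccccc1,III_aromatic_carbonyl,3,acetophenone
O=CC=O,III_aromatic_carbonyl,4,glyoxal (polyunsaturated carbonyl)
CC(=O)C(C)=O,III_aromatic_carbonyl,4,butane-2-3-dione
CC=CC(C)=O,III_aromatic_carbonyl,4,pent-3-en-2-one
O=CC=C,III_aromatic_carbonyl,4,acrolein
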