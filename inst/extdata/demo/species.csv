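code,scientific_name,family,life_form,origin,vernacular
BD,Baccharis dracunculifolia,Asteraceae,shrub,native,t'ola
BeC,Berberis commutata,Berberidaceae,shrub,native,churisik'e
BuC,Buddleja coriacea,Buddlejaceae,tree,native_cultivated,kishuara
CB,Clinopodium bolivianum,Lamiaceae,subshrub,native,chini munya
EG,Eucalyptus globulus,Myrtaceae,tree,exotic,eucalipto
GP,Gynoxys psilophylla,Asteraceae,tree,native,k'apa towi
KS,Kaunia saltensis,Asteraceae,shrub,native,jaya towi
LG,Lepechinia graveolens,Lamiaceae,shrub,native,raqacho
MO,Minthostachys ovata,Lamiaceae,subshrub,native,k'oa munya
PS,Polylepis subtusalbida,Rosaceae,tree,native,kewinya
PL,Prosopis laevigata,Leguminosae,tree,native,thaqo
SP,Sambucus peruviana,Caprifoliaceae,tree,exotic,sauco
SM,Schinus molle,Anacardiaceae,tree,native,molle
SA,Senna aymara,Leguminosae,shrub,native,motocho
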