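element,partition
premaxilla,skull
maxilla,skull
nasal,skull
prefrontal,skull
frontal,skull
postfrontal,skull
postorbital,skull
jugal,skull
squamosal,skull
parietal,skull
supratemporal,skull
quadrate,skull
vomer,skull
palatine,skull
pterygoid,skull
ectopterygoid,skull
braincase,skull
dentary,mandible
splenial,mandible
angular,mandible
surangular,mandible
coronoid,mandible
prearticular,mandible
articular,mandible
cervical_vertebrae,axial
dorsal_vertebrae,axial
sacral_vertebrae,axial
caudal_vertebrae,axial
ribs,axial
gastralia,axial
scapula,pectoral_girdle
coracoid,pectoral_girdle
clavicle,pectoral_girdle
interclavicle,pectoral_girdle
sternum,pectoral_girdle
humerus,forelimb
radius,forelimb
ulna,forelimb
carpals,forelimb
metacarpals,forelimb
manual_phalanges,forelimb
ilium,pelvic_girdle
ischium,pelvic_girdle
pubis,pelvic_girdle
femur,hindlimb
tibia,hindlimb
fibula,hindlimb
tarsals,hindlimb
metatarsals,hindlimb
pedal_phalanges,hindlimb
osteoderms,integument
scales,integument
feathers,integument
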