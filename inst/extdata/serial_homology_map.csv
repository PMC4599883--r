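upper_limb,lower_limb
Scapula,Hip bone
Humerus,Femur
Radius,Tibia
Ulna,Fibula
Scaphoid,Talus
Lunate,Navicular
Triquetrum,Calcaneus
Pisiform,Cuboid
Trapezium,Medial cuneiform
Trapezoid,Intermediate cuneiform
Capitate,Lateral cuneiform
Radial sesamoid,Medial sesamoid
Ulnar sesamoid,Lateral sesamoid
1st Metacarpal,1st Metatarsal
2nd Metacarpal,2nd Metatarsal
3rd Metacarpal,3rd Metatarsal
4th Metacarpal,4th Metatarsal
5th Metacarpal,5th Metatarsal
1st Palmar interossei,1st Plantar interossei
2nd Palmar interossei,2nd Plantar interossei
3rd Palmar interossei,3rd Plantar interossei
Flexor digitorum superficialis,Flexor digitorum brevis
Flexor digitorum profundus,Flexor digitorum longus
Extensor digitorum,Extensor digitorum longus
Extensor indicis,Extensor digitorum brevis
Flexor pollicis longus,Flexor hallucis longus
Extensor pollicis longus,Extensor hallucis longus
Extensor pollicis brevis,Extensor hallucis brevis
Abductor pollicis brevis,Abductor hallucis
Adductor pollicis,Adductor hallucis
Flexor pollicis brevis,Flexor hallucis brevis
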