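label,node_class,limb,region
Clavicle,bone_cartilage,UL,proximal
Scapula,bone_cartilage,UL,proximal
Humerus,bone_cartilage,UL,proximal
Radius,bone_cartilage,UL,distal
Ulna,bone_cartilage,UL,distal
Scaphoid,bone_cartilage,UL,distal
Lunate,bone_cartilage,UL,distal
Triquetrum,bone_cartilage,UL,distal
Pisiform,bone_cartilage,UL,distal
Trapezium,bone_cartilage,UL,distal
Trapezoid,bone_cartilage,UL,distal
Capitate,bone_cartilage,UL,distal
Hamate,bone_cartilage,UL,distal
Radial sesamoid,bone_cartilage,UL,distal
Ulnar sesamoid,bone_cartilage,UL,distal
1st Metacarpal,bone_cartilage,UL,distal
2nd Metacarpal,bone_cartilage,UL,distal
3rd Metacarpal,bone_cartilage,UL,distal
4th Metacarpal,bone_cartilage,UL,distal
5th Metacarpal,bone_cartilage,UL,distal
1st Proximal phalanx,bone_cartilage,both,distal
2nd Proximal phalanx,bone_cartilage,both,distal
3rd Proximal phalanx,bone_cartilage,both,distal
4th Proximal phalanx,bone_cartilage,both,distal
5th Proximal phalanx,bone_cartilage,both,distal
2nd Middle phalanx,bone_cartilage,both,distal
3rd Middle phalanx,bone_cartilage,both,distal
4th Middle phalanx,bone_cartilage,both,distal
5th Middle phalanx,bone_cartilage,both,distal
1st Distal phalanx,bone_cartilage,both,distal
2nd Distal phalanx,bone_cartilage,both,distal
3rd Distal phalanx,bone_cartilage,both,distal
4th Distal phalanx,bone_cartilage,both,distal
5th Distal phalanx,bone_cartilage,both,distal
Hip bone,bone_cartilage,LL,proximal
Ilium,bone_cartilage,LL,proximal
Ischium,bone_cartilage,LL,proximal
Pubis,bone_cartilage,LL,proximal
Femur,bone_cartilage,LL,proximal
Patella,bone_cartilage,LL,proximal
Tibia,bone_cartilage,LL,distal
Fibula,bone_cartilage,LL,distal
Talus,bone_cartilage,LL,distal
Calcaneus,bone_cartilage,LL,distal
Navicular,bone_cartilage,LL,distal
Cuboid,bone_cartilage,LL,distal
Medial cuneiform,bone_cartilage,LL,distal
Intermediate cuneiform,bone_cartilage,LL,distal
Lateral cuneiform,bone_cartilage,LL,distal
Medial sesamoid,bone_cartilage,LL,distal
Lateral sesamoid,bone_cartilage,LL,distal
1st Metatarsal,bone_cartilage,LL,distal
2nd Metatarsal,bone_cartilage,LL,distal
3rd Metatarsal,bone_cartilage,LL,distal
4th Metatarsal,bone_cartilage,LL,distal
5th Metatarsal,bone_cartilage,LL,distal
Deltoid,muscle,UL,proximal
Pectoralis major,muscle,UL,proximal
Pectoralis minor,muscle,UL,proximal
Subclavius,muscle,UL,proximal
Serratus anterior,muscle,UL,proximal
Levator scapulae,muscle,UL,proximal
Rhomboid major,muscle,UL,proximal
Rhomboid minor,muscle,UL,proximal
Rhomboid major minor,muscle,UL,proximal
Supraspinatus,muscle,UL,proximal
Infraspinatus,muscle,UL,proximal
Teres major,muscle,UL,proximal
Teres minor,muscle,UL,proximal
Subscapularis,muscle,UL,proximal
Latissimus dorsi,muscle,UL,proximal
Coracobrachialis,muscle,UL,proximal
Biceps brachii,muscle,UL,proximal
Brachialis,muscle,UL,proximal
Triceps brachii,muscle,UL,proximal
Anconeus,muscle,UL,proximal
Brachioradialis,muscle,UL,distal
Pronator teres,muscle,UL,distal
Pronator quadratus,muscle,UL,distal
Supinator,muscle,UL,distal
Palmaris longus,muscle,UL,distal
Flexor carpi radialis,muscle,UL,distal
Flexor carpi ulnaris,muscle,UL,distal
Extensor carpi radialis longus,muscle,UL,distal
Extensor carpi radialis brevis,muscle,UL,distal
Extensor carpi ulnaris,muscle,UL,distal
Extensor digitorum,muscle,UL,distal
Extensor digiti minimi,muscle,UL,distal
Extensor indicis,muscle,UL,distal
Abductor pollicis longus,muscle,UL,distal
Extensor pollicis longus,muscle,UL,distal
Extensor pollicis brevis,muscle,UL,distal
Flexor pollicis longus,muscle,UL,distal
Flexor digitorum superficialis,muscle,UL,distal
Flexor digitorum profundus,muscle,UL,distal
Abductor pollicis brevis,muscle,UL,distal
Flexor pollicis brevis,muscle,UL,distal
Opponens pollicis,muscle,UL,distal
Adductor pollicis,muscle,UL,distal
Adductor pollicis accessorius,muscle,UL,distal
Abductor digiti minimi,muscle,both,distal
Flexor digiti minimi brevis,muscle,both,distal
Opponens digiti minimi,muscle,UL,distal
1st Lumbrical,muscle,both,distal
2nd Lumbrical,muscle,both,distal
3rd Lumbrical,muscle,both,distal
4th Lumbrical,muscle,both,distal
1st Dorsal interossei,muscle,both,distal
2nd Dorsal interossei,muscle,both,distal
3rd Dorsal interossei,muscle,both,distal
4th Dorsal interossei,muscle,both,distal
1st Palmar interossei,muscle,UL,distal
2nd Palmar interossei,muscle,UL,distal
3rd Palmar interossei,muscle,UL,distal
Musculous interosseous accessorius,muscle,UL,distal
Iliopsoas,muscle,LL,proximal
Gluteus maximus,muscle,LL,proximal
Gluteus medius,muscle,LL,proximal
Gluteus minimus,muscle,LL,proximal
Tensor fasciae latae,muscle,LL,proximal
Piriformis,muscle,LL,proximal
Obturator internus,muscle,LL,proximal
Obturator externus,muscle,LL,proximal
Gemellus superior,muscle,LL,proximal
Gemellus inferior,muscle,LL,proximal
Quadratus femoris,muscle,LL,proximal
Pectineus,muscle,LL,proximal
Adductor longus,muscle,LL,proximal
Adductor brevis,muscle,LL,proximal
Adductor magnus,muscle,LL,proximal
Gracilis,muscle,LL,proximal
Sartorius,muscle,LL,proximal
Rectus femoris,muscle,LL,proximal
Vastus lateralis,muscle,LL,proximal
Vastus medialis,muscle,LL,proximal
Vastus intermedius,muscle,LL,proximal
Biceps femoris,muscle,LL,proximal
Semitendinosus,muscle,LL,proximal
Semimembranosus,muscle,LL,proximal
Popliteus,muscle,LL,proximal
Gastrocnemius,muscle,LL,distal
Soleus,muscle,LL,distal
Plantaris,muscle,LL,distal
Tibialis anterior,muscle,LL,distal
Tibialis posterior,muscle,LL,distal
Tiblialis posterior,muscle,LL,distal
Fibularis longus,muscle,LL,distal
Fibularis brevis,muscle,LL,distal
Fibularis tertius,muscle,LL,distal
Extensor digitorum longus,muscle,LL,distal
Extensor digitorum brevis,muscle,LL,distal
Extensor hallucis longus,muscle,LL,distal
Extensor hallucis brevis,muscle,LL,distal
Flexor digitorum longus,muscle,LL,distal
Flexor digitorum brevis,muscle,LL,distal
Flexor hallucis longus,muscle,LL,distal
Flexor hallucis brevis,muscle,LL,distal
Quadratus plantae,muscle,LL,distal
Abductor hallucis,muscle,LL,distal
Adductor hallucis,muscle,LL,distal
1st Plantar interossei,muscle,LL,distal
2nd Plantar interossei,muscle,LL,distal
3rd Plantar interossei,muscle,LL,distal
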