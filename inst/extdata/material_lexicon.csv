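term,category
mud,binder
sand,binder
saliva,binder
peat,binder
droppings,binder
dung,binder
clay,binder
resin,binder
feather,fibre
feathers,fibre
fur,fibre
hair,fibre
wool,fibre
plant down,fibre
down,fibre
moss,fibre
fern,fibre
fungi,fibre
fungus,fibre
rootlet,fibre
rootlets,fibre
lichen,fibre
grass,grass
grasses,grass
stem,grass
stems,grass
grassy vines,grass
spanish moss,grass
seaweed,grass
kelp,grass
algae,grass
sedge,grass
straw,grass
reed,grass
reeds,grass
leaf,leaf
leaves,leaf
pine needles,leaf
needles,leaf
shell,mineral
shells,mineral
bone,mineral
bones,mineral
pebble,mineral
pebbles,mineral
stone,mineral
stones,mineral
gravel,mineral
silk,silk
spider silk,silk
spider web,silk
cobweb,silk
cobwebs,silk
webbing,silk
cocoon silk,silk
twig,twig
twigs,twig
wood,twig
stick,twig
sticks,twig
root,twig
roots,twig
bark,twig
liana,twig
lianas,twig
woody vines,twig
heather,twig
branch,twig
branches,twig
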