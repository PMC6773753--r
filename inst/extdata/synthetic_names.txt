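emma
liam
olivia
noah
ava
mason
sophia
lucas
mia
ethan
harper
logan
ella
jacob
lily
aiden
chloe
daniel
zoe
owen
nora
caleb
isla
wyatt
ruby
eli
stella
henry
luna
oscar
violet
felix
ivy
jasper
clara
milo
alice
hugo
freya
leo
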