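class,SIT,STAND,LIE,WALK,RUN,UP,DOWN
SIT,100,0,0,0,0,0,0
STAND,0,100,0,0,0,0,0
LIE,20,0,80,0,0,0,0
WALK,0,0,0,65,25,7.5,2.5
RUN,0,0,0,0,100,0,0
UP,0,0,0,17.5,0,67.5,15
DOWN,0,2.5,0,22.5,0,30,45
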