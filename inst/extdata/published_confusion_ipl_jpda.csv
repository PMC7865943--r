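class,SIT,STAND,LIE,WALK,RUN,UP,DOWN
SIT,100,0,0,0,0,0,0
STAND,0,100,0,0,0,0,0
LIE,0,0,100,0,0,0,0
WALK,0,0,0,87.5,2.5,2.5,7.5
RUN,0,0,0,0,97.5,0,2.5
UP,0,0,0,12.5,0,75,12.5
DOWN,0,0,0,0,0,7.5,92.5
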