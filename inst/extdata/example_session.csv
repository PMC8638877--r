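"block","trial","condition","smiley_location","touched_location","correct","rt_ms","validity","n_touches"
1,1,"prepotent","top","top",TRUE,900,"valid",1
1,2,"prepotent","top","top",TRUE,1100,"invalid_intervention",1
1,3,"prepotent","top","top",TRUE,1300,"invalid_intervention",1
1,4,"prepotent","top","top",TRUE,1500,"invalid_intervention",1
1,5,"prepotent","top","top",TRUE,900,"invalid_intervention",1
1,6,"inhibitory","bottom","top",FALSE,1100,"valid",1
1,7,"prepotent","top","top",TRUE,1300,"invalid_intervention",1
1,8,"prepotent","top","top",TRUE,1500,"invalid_intervention",1
1,9,"prepotent","top","top",TRUE,900,"invalid_intervention",1
1,10,"prepotent","top","bottom",FALSE,1100,"valid",1
1,11,"inhibitory","bottom","top",FALSE,1300,"valid",1
1,12,"prepotent","top","bottom",FALSE,1500,"valid",1
1,13,"prepotent","top","bottom",FALSE,900,"valid",1
1,14,"prepotent","top","bottom",FALSE,1100,"valid",1
1,15,"prepotent","top","bottom",FALSE,1300,"valid",1
1,16,"prepotent","top","bottom",FALSE,1500,"valid",1
1,17,"inhibitory","bottom","top",FALSE,900,"valid",1
1,18,"prepotent","top","top",TRUE,1100,"valid",1
1,19,"prepotent","top","top",TRUE,1300,"valid",1
1,20,"prepotent","top","top",TRUE,1500,"valid",1
1,21,"inhibitory","bottom","top",FALSE,900,"valid",1
1,22,"prepotent","top","top",TRUE,1100,"valid",1
1,23,"prepotent","top","top",TRUE,1300,"valid",1
1,24,"prepotent","top","top",TRUE,1500,"valid",1
1,25,"inhibitory","bottom","bottom",TRUE,900,"valid",1
1,26,"prepotent","top","top",TRUE,1100,"valid",1
1,27,"prepotent","top","top",TRUE,1300,"valid",1
1,28,"inhibitory","bottom","bottom",TRUE,1500,"valid",1
1,29,"prepotent","top","top",TRUE,900,"valid",1
1,30,"inhibitory","bottom","bottom",TRUE,1100,"valid",1
1,31,"prepotent","top","top",TRUE,1300,"valid",1
1,32,"inhibitory","bottom","bottom",TRUE,1500,"valid",1
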