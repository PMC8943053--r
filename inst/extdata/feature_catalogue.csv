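feature,units,body_part,motion_mode,description
length,px,whole,all,median midline arc length of the track
width,px,midbody,all,mean pixel area divided by midline length
speed,px/s,whole,all,mean absolute signed crawling speed
frac_fw,fraction,whole,fw,fraction of frames classified forward
frac_bw,fraction,whole,bw,fraction of frames classified backward
frac_st,fraction,whole,st,fraction of frames classified stationary
speed_fw,px/s,whole,fw,mean signed speed over forward frames
speed_bw,px/s,whole,bw,mean signed speed over backward frames
curvature_head,rad/px,head,all,mean absolute midline curvature in the head fifth
curvature_neck,rad/px,neck,all,mean absolute midline curvature in the neck fifth
curvature_midbody,rad/px,midbody,all,mean absolute midline curvature in the midbody fifth
curvature_hips,rad/px,hips,all,mean absolute midline curvature in the hips fifth
curvature_tail,rad/px,tail,all,mean absolute midline curvature in the tail fifth
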