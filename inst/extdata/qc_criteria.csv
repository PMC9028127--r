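criterion,index,effect,operator_message,guidance
bev_limit,both,usability,Back-extrapolated volume exceeds the allowed limit (hesitant start of test).,Start blasting the air out immediately after the deep breath in; do not pause at full inflation.
fev1_measurable,fev1,usability,Recording ended before one full second of expiration; FEV1 cannot be measured.,Keep blowing hard for as long as you can; do not stop right after the start.
cough_first_second,fev1,usability,Cough detected within the first second of expiration; FEV1 is not reportable from this maneuver.,Try to avoid coughing while blowing out; take a short rest and drink some water before the next attempt.
glottic_closure_first_second,fev1,usability,Glottic closure detected within the first second of expiration.,Keep your throat open and keep pushing the air out; do not hold your breath during the blow.
flutter_first_second,fev1,usability,Flow oscillation (possible obstructed mouthpiece or device fault) within the first second.,Keep your tongue and teeth clear of the mouthpiece and keep a firm lip seal.
extra_breath_first_second,fev1,acceptability,Extra breath taken within the first second of expiration.,Take one deep breath in and blow it all out in one go; do not breathe in again while blowing.
extra_breath_any,fvc,usability,Extra breath taken during the maneuver; the volume record is corrupted.,Take one deep breath in and blow it all out in one go; do not breathe in again while blowing.
flutter_any,fvc,usability,Flow oscillation (possible obstructed mouthpiece or device fault) during the maneuver.,Keep your tongue and teeth clear of the mouthpiece and keep a firm lip seal.
eofe,fvc,acceptability,End of forced expiration not reached: no volume plateau and expiration neither long nor repeatable enough.,Keep squeezing the air out until you feel completely empty; the operator will tell you when to stop.
glottic_closure_any,fvc,acceptability,Glottic closure detected during the maneuver.,Keep your throat open and keep pushing the air out; do not hold your breath during the blow.
early_termination,fvc,acceptability,Expiration stopped early; no plateau and insufficient expiratory time.,Keep blowing until the operator tells you to stop; keep going even when little air seems to come out.
variable_flow,both,warning,Rise to peak flow was slow (variable flow); effort may be submaximal.,Blast the air out as hard and fast as you can right from the start.
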