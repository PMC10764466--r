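class_name,quality_estimate,excluded,chaos_group,vehicle_like,cry_like,babble_like
Silence,0.90,FALSE,non_high,FALSE,FALSE,FALSE
Breathing,0.55,FALSE,non_high,FALSE,FALSE,FALSE
Wind,0.62,FALSE,non_high,FALSE,FALSE,FALSE
Singing,0.71,FALSE,non_high,FALSE,FALSE,FALSE
Chime,0.68,FALSE,non_high,FALSE,FALSE,FALSE
Classical music,0.77,FALSE,non_high,FALSE,FALSE,FALSE
Piano,0.74,FALSE,non_high,FALSE,FALSE,FALSE
Raindrop,0.45,FALSE,non_high,FALSE,FALSE,FALSE
White noise,0.66,FALSE,non_high,FALSE,FALSE,FALSE
Shuffling cards,0.52,FALSE,non_high,FALSE,FALSE,FALSE
Tearing,0.48,FALSE,non_high,FALSE,FALSE,FALSE
Drip,0.41,FALSE,non_high,FALSE,FALSE,FALSE
Purr,0.58,FALSE,non_high,FALSE,FALSE,FALSE
Microwave,0.63,FALSE,non_high,FALSE,FALSE,FALSE
"Walk, footsteps",0.57,FALSE,non_high,FALSE,FALSE,FALSE
Speech,0.88,FALSE,non_high,FALSE,FALSE,FALSE
Babbling,0.47,FALSE,non_high,FALSE,FALSE,TRUE
"Child speech, kid speaking",0.69,FALSE,non_high,FALSE,FALSE,FALSE
Toilet flush,0.73,FALSE,non_high,FALSE,FALSE,FALSE
Electric shaver,0.61,FALSE,non_high,FALSE,FALSE,FALSE
Doorbell,0.67,FALSE,non_high,FALSE,FALSE,FALSE
Alarm clock,0.72,FALSE,non_high,FALSE,FALSE,FALSE
Hair dryer,0.64,FALSE,non_high,FALSE,FALSE,FALSE
Pop music,0.70,FALSE,non_high,FALSE,FALSE,FALSE
Acoustic guitar,0.75,FALSE,non_high,FALSE,FALSE,FALSE
"Violin, fiddle",0.71,FALSE,non_high,FALSE,FALSE,FALSE
Sink (filling or washing),0.59,FALSE,non_high,FALSE,FALSE,FALSE
Children shouting,0.78,FALSE,high,FALSE,FALSE,FALSE
Screaming,0.82,FALSE,high,FALSE,FALSE,FALSE
"Baby cry, infant cry",0.80,FALSE,high,FALSE,TRUE,FALSE
"Crying, sobbing",0.76,FALSE,high,FALSE,TRUE,FALSE
Car,0.74,FALSE,high,TRUE,FALSE,FALSE
Vehicle,0.65,FALSE,high,TRUE,FALSE,FALSE
"Traffic noise, roadway noise",0.60,FALSE,high,TRUE,FALSE,FALSE
Applause,0.79,FALSE,high,FALSE,FALSE,FALSE
Drum roll,0.66,FALSE,high,FALSE,FALSE,FALSE
Electronic music,0.68,FALSE,high,FALSE,FALSE,FALSE
Fire alarm,0.81,FALSE,high,FALSE,FALSE,FALSE
"Smash, crash",0.70,FALSE,high,FALSE,FALSE,FALSE
Chainsaw,0.73,FALSE,high,FALSE,FALSE,FALSE
Drill,0.62,FALSE,high,FALSE,FALSE,FALSE
"Inside, public space",0.44,FALSE,high,FALSE,FALSE,FALSE
Heart sounds,0.20,FALSE,non_high,FALSE,FALSE,FALSE
Pulse,0.15,FALSE,non_high,FALSE,FALSE,FALSE
Battle cry,0.30,FALSE,high,FALSE,FALSE,FALSE
Artillery fire,0.85,TRUE,high,FALSE,FALSE,FALSE
"Motorboat, speedboat",0.70,TRUE,high,TRUE,FALSE,FALSE
Eruption,0.77,TRUE,high,FALSE,FALSE,FALSE
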