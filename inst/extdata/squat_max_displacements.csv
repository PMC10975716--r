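subject,load_pct_bw,marker,max_displacement_cm
S01,0,barbell,56.0
S02,0,barbell,62.5
S03,0,barbell,65.3
S04,0,barbell,63.6
S05,0,barbell,63.0
S06,0,barbell,54.1
S07,0,barbell,79.3
S08,0,barbell,59.0
S09,0,barbell,72.7
S10,0,barbell,46.7
S01,0,hip,26.5
S02,0,hip,37.5
S03,0,hip,40.3
S04,0,hip,25.6
S05,0,hip,28.2
S06,0,hip,25.5
S07,0,hip,39.5
S08,0,hip,31.5
S09,0,hip,38.6
S10,0,hip,29.9
S01,0,knee,8.1
S02,0,knee,8.2
S03,0,knee,11.5
S04,0,knee,8.1
S05,0,knee,7.4
S06,0,knee,8.0
S07,0,knee,10.8
S08,0,knee,8.0
S09,0,knee,11.0
S10,0,knee,7.2
S01,0,ankle,0.5
S02,0,ankle,0.2
S03,0,ankle,0.6
S04,0,ankle,1.3
S05,0,ankle,0.6
S06,0,ankle,0.3
S07,0,ankle,0.2
S08,0,ankle,0.3
S09,0,ankle,0.4
S10,0,ankle,0.5
S01,50,barbell,59.6
S02,50,barbell,56.0
S03,50,barbell,65.6
S04,50,barbell,66.9
S05,50,barbell,67.1
S06,50,barbell,58.0
S07,50,barbell,75.5
S08,50,barbell,63.5
S09,50,barbell,75.7
S10,50,barbell,49.0
S01,50,hip,32.8
S02,50,hip,35.3
S03,50,hip,41.7
S04,50,hip,31.0
S05,50,hip,35.2
S06,50,hip,31.9
S07,50,hip,34.2
S08,50,hip,36.2
S09,50,hip,44.4
S10,50,hip,30.9
S01,50,knee,8.8
S02,50,knee,7.4
S03,50,knee,11.5
S04,50,knee,9.4
S05,50,knee,8.8
S06,50,knee,9.2
S07,50,knee,9.5
S08,50,knee,9.5
S09,50,knee,12.0
S10,50,knee,8.7
S01,50,ankle,0.3
S02,50,ankle,0.2
S03,50,ankle,0.7
S04,50,ankle,0.9
S05,50,ankle,0.5
S06,50,ankle,0.2
S07,50,ankle,0.3
S08,50,ankle,0.4
S09,50,ankle,0.4
S10,50,ankle,0.4
S01,75,barbell,56.0
S02,75,barbell,55.6
S03,75,barbell,62.3
S04,75,barbell,63.2
S05,75,barbell,69.1
S06,75,barbell,58.5
S07,75,barbell,65.8
S08,75,barbell,64.6
S09,75,barbell,79.3
S10,75,barbell,50.0
S01,75,hip,31.2
S02,75,hip,33.9
S03,75,hip,38.0
S04,75,hip,32.5
S05,75,hip,37.2
S06,75,hip,31.5
S07,75,hip,26.0
S08,75,hip,37.8
S09,75,hip,46.7
S10,75,hip,31.8
S01,75,knee,7.8
S02,75,knee,6.9
S03,75,knee,10.5
S04,75,knee,9.8
S05,75,knee,9.7
S06,75,knee,9.5
S07,75,knee,7.3
S08,75,knee,9.8
S09,75,knee,13.6
S10,75,knee,8.1
S01,75,ankle,0.4
S02,75,ankle,0.2
S03,75,ankle,0.6
S04,75,ankle,1.0
S05,75,ankle,0.5
S06,75,ankle,0.2
S07,75,ankle,0.6
S08,75,ankle,0.5
S09,75,ankle,0.5
S10,75,ankle,0.5
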