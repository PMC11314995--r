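Head:
- Top.Head
- Front.Head
- L.Head
- R.Head
Shoulders:
- L.Shoulder
- R.Shoulder
Thorax:
- C7
- T10
- Sternum
- L.Scapula
- R.Scapula
Pelvis:
- L.ASIS
- R.ASIS
- L.PSIS
- R.PSIS
- Sacrum
L_Dist_Arm:
- L.Forearm
- L.Wrist.Lat
- L.Wrist.Med
R_Dist_Arm:
- R.Forearm
- R.Wrist.Lat
- R.Wrist.Med
L_Hand:
- L.Wrist
- L.Thumb.M3
- L.Finger3.M3
- L.Finger5.M3
R_Hand:
- R.Wrist
- R.Thumb.M3
- R.Finger3.M3
- R.Finger5.M3
L_Prox_Arm:
- L.Bicep
- L.Tricep
- L.Elbow
- L.Elbow.Med
R_Prox_Arm:
- R.Bicep
- R.Tricep
- R.Elbow
- R.Elbow.Med
L_Dist_Leg:
- L.Shank
- L.Ankle
- L.Ankle.Med
R_Dist_Leg:
- R.Shank
- R.Ankle
- R.Ankle.Med
L_Foot:
- L.Heel
- L.Toe
- L.Foot.Lat
- L.Foot.Med
R_Foot:
- R.Heel
- R.Toe
- R.Foot.Lat
- R.Foot.Med
L_Prox_Leg:
- L.Thigh
- L.Thigh.Low
- L.Knee
- L.Knee.Med
R_Prox_Leg:
- R.Thigh
- R.Thigh.Low
- R.Knee
- R.Knee.Med
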