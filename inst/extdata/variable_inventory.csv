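variable_id,label,block,domain,direction,mean,sd,distortion
st_stride_regularity,Single task stride regularity (NU),motor,variability,higher,0.75,0.10,identity
st_stride_time_var,Single task stride time variability (%),motor,variability,lower,1.60,0.73,exponential
dt_stride_regularity,Dual task stride regularity (NU),motor,variability,higher,0.60,0.19,identity
dt_stride_time_var,Dual task stride time variability (%),motor,variability,lower,2.73,2.39,exponential
sts_range_ap,Sit to stand range anterior-posterior (g),motor,transition,lower,1.78,1.80,exponential
sts_jerk_ap,Sit to stand jerk anterior-posterior (g/s),motor,transition,lower,2.47,5.02,heavy-tail
sts_pitch_amp,Sit to stand pitch amplitude (deg/s),motor,transition,higher,-61.87,38.37,identity
stand_to_sit_pitch_amp,Stand to sit pitch amplitude (deg/s),motor,transition,higher,58.30,28.38,identity
turn_yaw_amplitude,Turn yaw amplitude (deg/s),motor,turn,higher,182.20,37.80,identity
turn_yaw_duration,Turn yaw duration (s),motor,turn,lower,1.63,0.44,exponential
st_step_regularity,Single task step regularity (NU),motor,asymmetry,higher,0.59,0.15,identity
st_step_symmetry,Single task step symmetry (NU),motor,asymmetry,lower,0.77,0.23,identity
dt_step_symmetry,Dual task step symmetry (NU),motor,asymmetry,lower,0.87,0.35,identity
dt_step_regularity,Dual task step regularity (NU),motor,asymmetry,higher,0.52,0.18,identity
st_stride_time_avg,Single task stride average (s),motor,rhythm,lower,1.12,0.10,identity
dt_stride_time_avg,Dual task stride average (s),motor,rhythm,lower,1.23,0.16,identity
st_stride_length,Single task stride length (m),motor,pace,higher,1.13,0.20,identity
st_gait_speed,Single task gait speed (m/s),motor,pace,higher,0.93,0.20,identity
dt_stride_length,Dual task stride length (m),motor,pace,higher,1.15,0.20,identity
tug_ap_duration,Timed up and go anterior-posterior duration (s),motor,pace,lower,10.80,2.11,identity
tug_duration,Timed up and go duration (s),motor,pace,lower,6.15,1.85,exponential
phonemic_fluency,Phonemic fluency (total correct),cognitive,executive,higher,47.04,12.85,identity
tmt_b,Trail making test part B (s),cognitive,executive,lower,70.23,33.92,exponential
wais3_mr,WAIS-3 matrix reasoning (total correct),cognitive,executive,higher,15.79,5.25,identity
wais3_bd,WAIS-3 block design (total correct),cognitive,executive,higher,38.52,12.71,identity
wcst_persev_err,WCST perseverative errors (total),cognitive,executive,lower,6.48,6.24,exponential
paper_folding,Paper folding (prop. on-time correct),cognitive,executive,higher,0.51,0.26,bounded
letter_set,Letter set (prop. on-time correct),cognitive,executive,higher,0.72,0.22,bounded
matrix_reasoning,Matrix reasoning (prop. on-time correct),cognitive,executive,higher,0.47,0.27,bounded
cpt_correct_ratio,Continuous performance test correct ratio,cognitive,executive,higher,97.91,3.49,bounded
set_shifting,Set shifting shift trials score,cognitive,executive,higher,7.95,0.71,identity
flanker,Flanker adjusted composite score,cognitive,executive,higher,8.40,0.66,identity
gp_dominant,Grooved pegboard dominant hand (s),cognitive,speed,lower,82.73,27.41,exponential
gp_nondominant,Grooved pegboard non-dominant hand (s),cognitive,speed,lower,93.04,29.37,exponential
tmt_a,Trail making test part A (s),cognitive,speed,lower,27.72,10.69,exponential
waisr_ds,WAIS-R digit symbol (total correct),cognitive,speed,higher,52.13,12.94,identity
digit_symbol_rt,Digit symbol (median correct RT ms),cognitive,speed,lower,1571.57,233.41,identity
letter_comparison_rt,Letter comparison (median correct RT ms),cognitive,speed,lower,1731.30,238.33,identity
pattern_comparison_rt,Pattern comparison (median correct RT ms),cognitive,speed,lower,1608.31,241.77,identity
srt_last_trial,Selective reminding last trial (total correct),cognitive,memory,higher,9.87,2.15,identity
srt_delayed,Selective reminding delayed recall,cognitive,memory,higher,8.27,2.85,identity
logical_memory,Logical memory (prop. on-time correct),cognitive,memory,higher,0.72,0.19,bounded
paired_associates,Paired associates (prop. on-time correct),cognitive,memory,higher,0.68,0.22,bounded
word_order,Word order (prop. on-time correct),cognitive,memory,higher,0.45,0.19,bounded
amnart_errors,AMNART errors,cognitive,language,lower,10.25,9.05,exponential
wtar,WTAR (total correct),cognitive,language,higher,40.52,9.35,identity
waisr_vocabulary,WAIS-R vocabulary,cognitive,language,higher,58.18,9.60,identity
category_fluency,Category fluency (total correct),cognitive,language,higher,22.70,5.27,identity
synonyms,Synonyms (prop. on-time correct),cognitive,language,higher,0.69,0.20,bounded
antonyms,Antonyms (prop. on-time correct),cognitive,language,higher,0.58,0.23,bounded
picture_naming,Picture naming (prop. on-time correct),cognitive,language,higher,0.56,0.19,bounded
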