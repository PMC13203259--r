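construct,pole,word
GoalSpec,pos,kg
GoalSpec,pos,bmi
GoalSpec,pos,pace
GoalSpec,pos,minutes
GoalSpec,pos,calories
GoalSpec,pos,heart_rate
GoalSpec,neg,lose_weight
GoalSpec,neg,get_stronger
GoalSpec,neg,look_better
GoalSpec,neg,look_attractive
GoalSpec,neg,feel_better
GoalDiff,pos,difficult
GoalDiff,pos,grit_teeth
GoalDiff,pos,tearing
GoalDiff,pos,breakthrough
GoalDiff,pos,overcome
GoalDiff,pos,limit
GoalDiff,neg,basic
GoalDiff,neg,beginner
GoalDiff,neg,entry_level
GoalDiff,neg,activation
GoalDiff,neg,soothing
GoalDiff,neg,easy
GoalCommit,pos,determination
GoalCommit,pos,firm_resolve
GoalCommit,pos,persistence
GoalCommit,pos,plan
GoalCommit,pos,follow_through
GoalCommit,pos,deliver
GoalCommit,neg,delay
GoalCommit,neg,hesitation
GoalCommit,neg,interruption
GoalCommit,neg,termination
GoalCommit,neg,retreat
MastExp,pos,success
MastExp,pos,achievement
MastExp,pos,victory
MastExp,pos,reach_target
MastExp,pos,complete
MastExp,neg,failure
MastExp,neg,give_up
MastExp,neg,lose_control
MastExp,neg,stall
MastExp,neg,come_to_end
VicExp,pos,seek_help
VicExp,pos,ask_advice
VicExp,pos,consult
VicExp,pos,expert
VicExp,pos,senior
VicExp,pos,imitate
VicExp,pos,refer_to
VicExp,pos,template
VicExp,neg,alone
VicExp,neg,no_one_to_teach
VicExp,neg,rely_on_feeling
VicExp,neg,grope_way
VicExp,neg,fool_around
VicExp,neg,act_blindly
SocPer,pos,recognition
SocPer,pos,support
SocPer,pos,affirmation
SocPer,pos,encouragement
SocPer,pos,praise
SocPer,pos,compliment
SocPer,pos,trust
SocPer,neg,denial
SocPer,neg,doubt
SocPer,neg,ridicule
SocPer,neg,sarcasm
SocPer,neg,mockery
SocPer,neg,neglect
SocPer,neg,disheartened
PhyState,pos,vitality
PhyState,pos,energy
PhyState,pos,happiness
PhyState,pos,confidence
PhyState,pos,fully_energized
PhyState,pos,alert
PhyState,pos,high_spirited
PhyState,neg,weakness
PhyState,neg,drowsiness
PhyState,neg,fatigue
PhyState,neg,stress
PhyState,neg,self_abasement
PhyState,neg,listlessness
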