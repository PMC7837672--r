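index,left_anchor,right_anchor,factor,sign,state
1,Efficient,Inefficient,inefficient,1,FALSE
2,Organized,Unorganized,inefficient,1,FALSE
3,Productive,Unproductive,inefficient,1,FALSE
4,Focused,Distracted,inefficient,1,TRUE
5,Determined,Aimless,inefficient,1,TRUE
6,Clear headed,Confused,inefficient,1,FALSE
7,Bored,Engaged,inefficient,-1,TRUE
8,Optimistic,Pessimistic,negative,1,TRUE
9,Positive,Negative,negative,1,FALSE
10,Sad,Happy,negative,-1,FALSE
11,Lonely,Connected,negative,-1,TRUE
12,Proud,Ashamed,negative,1,TRUE
13,Calm,Anxious,calm,-1,FALSE
14,Stressed,Relaxed,calm,1,FALSE
15,Frustrated,Content,calm,1,TRUE
16,Healthy,Unhealthy,unhealthy,1,FALSE
17,Energetic,Tired,unhealthy,1,TRUE
18,Conservative,Progressive,thrill,1,FALSE
19,Cautious,Thrill seeking,thrill,1,TRUE
20,Impulsive,Intentional,intentional,1,TRUE
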