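load,efficiency,recommendation
low,low,"There may be situations in which the athlete is not serious or just to deal with the training. It is recommended to urge the training to be carried out normally."
low,medium,"The more ideal training state"
low,high,"Ideal training state, it is recommended to study its training methods and promote"
medium,low,"The effect is poor, which may be related to the training method or the layout of the training ground. It is recommended to replace the training program."
medium,medium,"The ideal training state"
medium,high,"The more ideal training state"
high,low,"Athletes may have physiological hidden dangers, it is recommended to check the record in a timely manner"
high,medium,"There may be room for improvement in the training method, or the physical condition on the day is general, and appropriate rest should be paid attention to."
high,high,"It is recommended to control the length of training, take appropriate rest, and beware of excessive fatigue."
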