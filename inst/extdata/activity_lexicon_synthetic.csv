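activity,word,rating_a,rating_b
religion,church,relevant,relevant
religion,pray,relevant,relevant
religion,god,relevant,relevant
religion,faith,relevant,irrelevant
religion,blessed,irrelevant,irrelevant
religion,worship,relevant,irrelevant
holiday,vacation,relevant,relevant
holiday,trip,relevant,irrelevant
holiday,beach,irrelevant,irrelevant
holiday,travel,relevant,irrelevant
holiday,christmas,relevant,relevant
talk_to_friend,friend,relevant,relevant
talk_to_friend,chat,relevant,relevant
talk_to_friend,gossip,irrelevant,irrelevant
talk_to_friend,catchup,relevant,irrelevant
talk_to_friend,buddy,irrelevant,relevant
chores,vacuum,relevant,relevant
chores,dishes,relevant,relevant
chores,laundry,relevant,relevant
chores,cleaning,relevant,irrelevant
chores,mowing,irrelevant,irrelevant
chores,ironing,irrelevant,irrelevant
family,mom,relevant,relevant
family,dad,relevant,relevant
family,sister,relevant,irrelevant
family,brother,irrelevant,irrelevant
family,cousin,irrelevant,irrelevant
meal,dinner,relevant,relevant
meal,lunch,relevant,irrelevant
meal,breakfast,irrelevant,irrelevant
meal,pizza,irrelevant,relevant
meal,recipe,relevant,irrelevant
school,school,relevant,relevant
school,exam,relevant,irrelevant
school,homework,relevant,relevant
school,lecture,irrelevant,irrelevant
school,essay,irrelevant,irrelevant
maths,maths,relevant,irrelevant
maths,algebra,irrelevant,irrelevant
maths,calculus,relevant,irrelevant
maths,equation,irrelevant,relevant
maths,geometry,irrelevant,irrelevant
death_disease,funeral,relevant,relevant
death_disease,cancer,relevant,relevant
death_disease,hospital,relevant,irrelevant
death_disease,illness,irrelevant,irrelevant
death_disease,grief,irrelevant,irrelevant
death_disease,disease,irrelevant,irrelevant
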