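class	phenomenon	template
defect	plain	{fpp} {childword} has {term} and {tp} is the bravest kid we know
defect	plain	so {emo} of {fpp} {childword} fighting {term} every single day
defect	plain	{fpp} {childword} was born with {term} and we love {tp} endlessly
defect	plain	one year since {fpp} {childword} got the {term} diagnosis still so {emo}
defect	plain	{fpp} little warrior beat another {term} surgery today feeling {emo}
defect	hashtag_fused	{fpp} {hterm} cutie is the light of this house
defect	hashtag_fused	{tp} sweet face {hfused} {hterm}
defect	hashtag_fused	best day at the park with {fpp} little one {hterm} {hfused}
defect	modifier_interrupted	the decision we made for {fpp} unborn {childword} with {term} was the hardest
defect	modifier_interrupted	{fpp} sweet little {childword} has {term} and never stops smiling
defect	implicit	born at twentysix weeks {term} and two surgeries later {fpp} warrior is home
defect	implicit	{term} journey update {fpp} little fighter had surgery this morning
possible_defect	name_deixis	{name} was diagnosed with {term} and had surgery to repair it
possible_defect	name_deixis	scheduling an appointment for {name} to confirm a {term} diagnosis
possible_defect	name_deixis	praying for {name} before the {term} operation tomorrow
possible_defect	name_deixis	{name} had another checkup for the {term} today
possible_defect	pronoun	{tp} has {term} but the doctors say {tp} is doing fine
possible_defect	pronoun	just in love with this little boy {term} split cerebellum and still smiling
possible_defect	hedge	the doctor said it could be {term} we will know more next week
possible_defect	hedge	they think it might be {term} waiting on the scan results
possible_defect	no_referent	born at twentyfive weeks hole in heart {term} and healed
non_defect	reported_speech	{name} says my {childword} has {term} but i would not change a thing via {user}
non_defect	reported_speech	{name} on raising a {childword} with {term} read the full story {url}
non_defect	reported_speech	watch {name} talk about life with {term} via {user}
non_defect	fundraiser	donate now to help children with {term} {url}
non_defect	fundraiser	support research into {term} this awareness month {url}
non_defect	fundraiser	retweet to raise awareness for kids living with {term}
non_defect	fundraiser	our charity walk for {term} families starts saturday {url}
non_defect	headline	new study links {term} to environmental factors {url}
non_defect	headline	hospital opens dedicated clinic for {term} patients {url}
non_defect	headline	researchers report progress in understanding {term} {url}
non_defect	headline	lawmakers debate coverage for {term} treatment {url}
non_defect	info	did you know {term} affects one in every thousand births
non_defect	info	fact of the day {term} can often be detected during pregnancy
non_defect	info	learn the warning signs of {term} at our webinar next week {url}
non_defect	info	five things every parent should know about {term} {url}
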