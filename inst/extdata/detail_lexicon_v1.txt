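# Episodic-detail cue lexicon, version 1.
# One single-word cue per line, grouped by category section. Matching is
# case-insensitive on whole word tokens. Category precedence when several
# sections fire on one chunk: place > time > perceptual > thought_emotion >
# event; a chunk with no cues is non_episodic.
version: 1

[place]
park
kitchen
office
beach
school
restaurant
downtown
garden
gym
library
cafe
museum
street
river
station
rooftop
market
church
hospital
bakery
plaza
trail
lake

[time]
morning
afternoon
evening
night
noon
midnight
yesterday
weekend
hour
hours
minute
minutes
monday
tuesday
wednesday
thursday
friday
saturday
sunday
dawn
dusk
early
late
springtime
midweek

[perceptual]
saw
heard
smelled
tasted
touched
bright
loud
quiet
sweet
bitter
cold
warm
soft
rough
noisy
shiny
fragrant
glowing
sounded
deafening
salty
icy
dazzling
echoing

[thought_emotion]
felt
feel
thought
think
believed
wondered
worried
nervous
happy
sad
anxious
proud
grateful
angry
scared
relieved
hoped
glad
upset
frustrated
embarrassed
confident
ashamed
thrilled

[event]
went
ate
walked
ran
played
met
visited
cooked
bought
drove
talked
helped
watched
finished
made
called
cleaned
worked
joined
attended
danced
swam
baked
wrote
painted
packed
practiced
celebrated
repaired
planted
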