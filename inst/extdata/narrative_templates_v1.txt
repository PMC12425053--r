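# Category-tagged narrative templates, version 1.
# Each line under an episodic/non-episodic section is a single-clause sentence
# that the rule_reference scorer classifies into exactly that section's
# category under detail_lexicon_v1. The [title] section holds short event
# titles and is never scored.
version: 1

[event]
I played soccer with my brother.
We cooked dinner together.
I met an old classmate.
They helped me carry the boxes.
We watched a documentary about whales.
I bought groceries for everyone.
She drove us across town.
I walked the dog twice.

[place]
We sat together in the kitchen.
The whole thing took place at the park.
I stopped by the library on my way.
The gathering was at a small restaurant.
My desk at the office was a mess.
We ended up near the river.
The class was held at the gym.
Everyone crowded into the garden.

[time]
It started early in the morning.
The visit lasted almost two hours.
Everything wrapped up by midnight.
This happened on Saturday.
We got there around noon.
It was already late in the evening.
The session ran for forty minutes.
It took most of the afternoon.

[thought_emotion]
I felt nervous about it.
I was proud of myself.
She seemed genuinely happy for us.
I worried that it would fail.
He thought it was a mistake.
I felt grateful more than anything.
Part of me was anxious.
I wondered what would come next.

[perceptual]
The music sounded very loud.
I smelled fresh bread somewhere close.
The light was harsh and bright.
Everything tasted slightly bitter.
The air felt cold on my skin.
I heard laughter from the next room.
The fabric was soft under my fingers.
A quiet hum filled the space.

[non_episodic]
That is usually how things go.
It was a pretty typical situation.
These things tend to come up.
Overall it was not a big deal.
That much was obvious to everyone.
There is not much else to say.
It is what it is.
Nothing about this was unusual.

[title]
coffee with a friend
grocery run
team meeting
evening jog
phone call with mom
board game night
bus commute
new recipe attempt
museum trip
laundry day
neighborhood walk
study session
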