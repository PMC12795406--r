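affect
assessment
assistance
attention
bodily_action
caretaking
change_of_state
cognition
communication
competition
consumption
contact
creation
deixis
desire
destruction
emotion
exchange
existence
experience
grooming
imitation
ingestion
interaction
judgement
locomotion
manipulation
measurement
motion
naming
obligation
perception
performance
placement
play
possession
pursuit
quantification
removal
rest
search
sensation
social_action
speech
transfer
use
utterance_act
weather
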