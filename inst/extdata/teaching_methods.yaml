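# Menu of teaching methods, one block per diagnostic, numbered so every
# rendered recommendation is traceable to (metric, method number).
# Placeholders in {braces} are filled with participant display names from
# the current group's data; a template whose placeholder has no data for
# this group is still rendered, with the placeholder text generalized.
isolates:
  - "Pair {isolates} with highly connected group members (such as {hubs}) in small group activities during the session."
  - "Call on {isolates} first to answer questions during the session so they do not fade into the background, and refer back to what they said to show their input is valued."
  - "Catch {isolates} alone if possible and check in privately about how the program is going for them, without putting them on the spot publicly."
degree_min:
  - "Pair highly connected group members ({hubs}) with less-connected members ({low_degree}) in small group activities during the session."
reciprocity_nonnull:
  - "Pair the members of one-way ties in small group activities: {unreciprocated}."
excess_components:
  - "Pair members from different subgroups in small group activities to create bridges: {bridges}."
  - "Make sure small groups do not split along subgroup lines ({subgroups}); if they do, reassign members."
density:
  - "Begin each session with an interactive, personalized, community-building ice-breaker."
  - "Use a talking-stick object (e.g., a beach ball) so each participant gets the opportunity to be part of the conversation."
  - "Help the group establish a stronger group identity: emphasize the group as a support network with a shared mission, the balance between what people put in and get out, that every member needs and deserves support, and the group's dedication to the shared goal."
  - "Spend 15 minutes so each member is offered the opportunity to share a relevant aspect of their lives and expectations, using a mutual-invitation process to structure the sharing."
  - "Facilitate making and meeting a shared common goal."
centralization:
  - "Do not let the most central member ({central}) start conversations, be the first to answer a question, or lead reviews and activities; redirect those roles to members on the periphery."
  - "Avoid pairing the most central member ({central}) with isolates."
transitivity_pct:
  - "Bring open triads together in session activities: when one member is tied to two others who are not tied to each other, connect those two."
cohesion_compactness:
  - "Challenge the group to make and meet a shared common goal (e.g., a weekly activity challenge), tracking and totalling the group's combined effort at each session and raising the goal as it is met."
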