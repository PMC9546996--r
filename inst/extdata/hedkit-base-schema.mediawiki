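HED version="1.0.0"

* Event [Something that happens at a point or span of recording time]
** Sensory-event {suggestedTag=Sensory-presentation} [Something perceivable by the participant occurred]
** Agent-action [An agent, usually the participant, does something]
** Data-feature [A pattern noted in the recorded data itself]
** Experiment-control [The experiment controller changes state]
** Experiment-procedure [A procedural step such as instruction or setup]
** Environmental-event [An uncontrolled change in the environment]
** Measurement-event [A measurement is taken]
* Agent [An entity that can act]
** Human-agent
** Animal-agent
** Avatar-agent
** Controller-agent
** Robotic-agent
** Software-agent
* Action [Something an agent does]
** Communicate
** Move
** Perceive
** Perform
** Think
* Item [A concrete or language thing]
** Biological-item
** Language-item
** Object
*** Geometric-object
**** 2D-shape
***** Triangle
***** Square
***** Rectangle
***** Ellipse
**** 3D-shape
*** Man-made-object {extensionAllowed}
*** Natural-object
** Sound
* Property [An attribute that modifies an item or event]
** Agent-property
** Data-property
*** Duration [Temporal extent of an enduring event]
**** # {takesValue, unitClass=time}
*** Delay [Time offset relative to the anchoring event]
**** # {takesValue, unitClass=time}
*** Temporal-marker
**** Onset [Marks the start of an enduring event]
**** Offset [Marks the end of an enduring event]
*** Spatial-extent
**** Width
***** # {takesValue, unitClass=physicalLength}
**** Height
***** # {takesValue, unitClass=physicalLength}
** Environmental-property
** Informational-property
*** Label
**** # {takesValue}
*** Description
**** # {takesValue}
*** Metadata
**** CogAtlas
***** # {takesValue}
**** CogPo
***** # {takesValue}
** Organizational-property
*** Definition [Declares a named, reusable tag group]
**** # {takesValue}
*** Def [References a named definition]
**** # {takesValue}
*** Def-expand [Marks the expanded contents of a definition]
**** # {takesValue}
*** Event-context [Holds copies of annotations of ongoing enduring events]
*** Recording [Organizes metadata that applies to the whole recording]
*** Task [Organizes the structured activity the participant performs]
*** Time-block [Organizes a contiguous block of recording time]
*** Condition-variable [Organizes an experimental condition in effect]
*** Experimental-trial [Organizes the events of one trial]
**** # {takesValue}
** Sensory-property
*** Sensory-presentation
**** Visual-presentation
**** Auditory-presentation
**** Tactile-presentation
*** Sensory-attribute
**** Color {relatedTag=Visual-presentation}
***** Red
***** Green
***** Blue
** Task-property
*** Task-event-role
**** Experimental-stimulus
**** Participant-response
**** Feedback
* Relation [Links two items or events]
** Comparative-relation
** Connective-relation
** Directional-relation
** Spatial-relation
** Temporal-relation

!# unit-classes
* time: s, ms
* physicalLength: m, cm, mm
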