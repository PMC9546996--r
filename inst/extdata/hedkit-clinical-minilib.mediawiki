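HED version="0.1.0" library="clinical-demo"

* Base [Synthetic demonstration library for clinical data-feature terms]
** Spike [A transient sharp waveform noted by a reviewer]
** Sharp-wave
** Sleep-spindle
* Modifier
** Interictal
** Artifactual
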