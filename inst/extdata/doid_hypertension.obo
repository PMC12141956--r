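format-version: 1.2
ontology: doid-excerpt

[Term]
id: DOID:10763
name: hypertension
synonym: "HTN" EXACT []
synonym: "hyperpiesia" EXACT []
synonym: "hypertensive disease" RELATED []
synonym: "vascular hypertensive disorder" EXACT []

[Term]
id: DOID:11734
name: epistaxis
synonym: "nosebleed" EXACT []

[Term]
id: DOID:9999999
name: retired disease concept
is_obsolete: true
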