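# Synthetic snapshot of the expert-curated keyword vocabulary (32 entries).
# Canonical name -> variant surface string(s); variants are normalized into
# token n-grams at load time. Replace with your own curated list via
# load_term_vocabulary(path, "keyword").
tau deposition: tau deposition
tau phosphorylation: tau phosphorylation
innate immune response: innate immune response
mitochondria: mitochondria
lipid metabolism: lipid metabolism
oxidative stress: oxidative stress
blood-brain barrier: blood-brain barrier
amyloid beta: amyloid beta
neuroinflammation: neuroinflammation
synaptic plasticity: synaptic plasticity
autophagy: autophagy
apoptosis: apoptosis
microglia: microglia
astrocyte activation: astrocyte activation
complement activation: complement activation
neurofibrillary tangles: neurofibrillary tangles
amyloid precursor protein: amyloid precursor protein
cholesterol metabolism: cholesterol metabolism
insulin signaling: insulin signaling
calcium homeostasis: calcium homeostasis
endoplasmic reticulum stress: endoplasmic reticulum stress
proteasome: proteasome
mitophagy: mitophagy
synaptic loss: synaptic loss
cognitive decline: cognitive decline
neuronal death: neuronal death
glucose metabolism: glucose metabolism
gut microbiome: gut microbiome
epigenetics: epigenetics
dna methylation: dna methylation
exosomes: exosomes
myelination: myelination
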