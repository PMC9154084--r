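label,iri,comment
pollinates,http://purl.obolibrary.org/obo/RO_0002455,animal acts on plant
pollinated by,http://purl.obolibrary.org/obo/RO_0002456,plant acts on animal (inverse)
visits flowers of,http://purl.obolibrary.org/obo/RO_0002623,animal acts on plant
flowers visited by,http://purl.obolibrary.org/obo/RO_0002624,plant acts on animal (inverse)
visits,http://purl.obolibrary.org/obo/RO_0002618,animal acts on plant
visited by,http://purl.obolibrary.org/obo/RO_0002619,plant acts on animal (inverse)
interacts with,http://purl.obolibrary.org/obo/RO_0002434,symmetric
biotically interacts with,http://purl.obolibrary.org/obo/RO_0002574,symmetric
preys on,http://purl.obolibrary.org/obo/RO_0002439,predator acts on prey
ecologically related to,http://purl.obolibrary.org/obo/RO_0002321,broadest fallback
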