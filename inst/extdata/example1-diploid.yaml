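# Reference configuration: additive-only diploid scheme, 100% bi-allelic
# QTL, reduced (desk) panel sizes.
example: 1
ploidy: 2
allelism: bi100
scale: desk
selection_model: additive
trait:
  varA: 1.0
  varE: 2.0
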