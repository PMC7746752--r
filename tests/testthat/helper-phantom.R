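# Small phantom configurations used across tests. Anatomy is fixed in mm,
# so fast configurations use coarser spacing rather than a smaller head.
fastSpec <- function(...) {
  phantomSpec(gridSize = 64L, voxelSpacingMm = 3, ...)
}
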