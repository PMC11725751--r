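# Shared vocabulary, loaded before every other source file.

# Canonical primal-cut order used throughout the package.
PRIMAL_CUTS <- c("shoulder_blade", "shoulder_picnic", "loin", "belly", "ham")

# Pig-table column carrying each cut's weight.
cut_column <- function(cut) paste0(cut, "_kg")

PIG_GROUPS <- c("I", "II", "III", "IV")
FARM_GRADES <- c("A", "B", "C", "D")
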