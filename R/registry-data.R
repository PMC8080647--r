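# Curated default gene-set membership.
#
# Category sizes are fixed by the analysis design: TREX 16, TREX-2 5,
# TREX-AFs 8, NPC 31, NTR 11, RAN 4, MARKER 2. Member lists are curated from
# the standard mRNA-export / nucleocytoplasmic-transport literature (THO/TREX
# and TREX-2 composition reviews, the human nucleoporin inventory, the
# karyopherin-beta family, and the Ran GTPase cycle); they are a
# literature-based stand-in for any particular published supplementary list
# and can be replaced wholesale via a GMT file (see [parse_gmt()]).

.SENQUAD_TREX <- c(
  # THO core
  "THOC1", "THOC2", "THOC3", "THOC5", "THOC6", "THOC7",
  # RNA helicases and export adaptors travelling with THO
  "DDX39A", "DDX39B", "ALYREF", "SARNP", "CHTOP", "POLDIP3",
  "ZC3H11A", "LUZP4", "FYTTD1", "ERH"
)

.SENQUAD_TREX2 <- c("MCM3AP", "PCID2", "SEM1", "ENY2", "CETN2")

# NXF/NXT transporter families plus the RBM15 adaptors
.SENQUAD_TREXAF <- c(
  "NXF1", "NXT1", "NXT2", "NXF2", "NXF3", "NXF5", "RBM15", "RBM15B"
)

.SENQUAD_NPC <- c(
  # Y complex (coat/scaffold)
  "NUP107", "NUP133", "NUP160", "NUP85", "NUP43", "NUP37",
  "SEC13", "SEH1L", "NUP98",
  # inner ring scaffold
  "NUP205", "NUP188", "NUP155", "NUP93", "NUP35",
  # central channel FG
  "NUP62", "NUP54", "NUPL1",
  # cytoplasmic side
  "NUP214", "NUP88", "RANBP2", "NUPL2",
  # nuclear side / basket
  "NUP153", "NUP50", "TPR",
  # transmembrane
  "NDC1", "POM121", "POM121C", "NUP210",
  # peripheral / mRNA-export-associated nucleoporins
  "AAAS", "RAE1", "GLE1"
)

.SENQUAD_NPC_SUBCLASS <- list(
  NPC_Y = c("NUP107", "NUP133", "NUP160", "NUP85", "NUP43", "NUP37",
            "SEC13", "SEH1L", "NUP98"),
  NPC_FG_CENTRAL = c("NUP62", "NUP54", "NUPL1"),
  NPC_FG_NUCLEAR = c("NUP153", "NUP50"),
  NPC_FG_CYTOPLASMIC = c("NUP214", "RANBP2", "NUPL2"),
  NPC_TM = c("NDC1", "POM121", "POM121C", "NUP210"),
  NPC_BASKET = c("TPR", "NUP153", "NUP50"),
  # extremely long-lived nucleoporins: the scaffold (Y complex + inner ring)
  # nucleoporins with protein half-lives beyond months; overlaps the other
  # subclasses by design (orthogonal classification)
  NPC_ELLP = c("NUP107", "NUP133", "NUP160", "NUP85", "NUP43", "NUP37",
               "SEC13", "SEH1L", "NUP205", "NUP188", "NUP155", "NUP93")
)

# karyopherin-beta family transport receptors ("Kaps"/NTRs)
.SENQUAD_NTR <- c(
  "KPNB1", "TNPO1", "TNPO2", "TNPO3", "IPO4", "IPO5", "IPO7",
  "IPO8", "IPO9", "IPO11", "IPO13"
)

.SENQUAD_RAN <- c("RAN", "RANBP1", "RANGAP1", "RCC1")

.SENQUAD_MARKER <- c("CDKN1A", "CDKN2A")
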