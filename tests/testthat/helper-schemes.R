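# Shared fixtures: schemes are loaded once per test run; random sequences
# are drawn from the 20 standard residues so external oracles (which may
# differ on ambiguity codes) stay comparable.
bl62 <- loadBuiltinScheme("blosum62", 11, 1)
bl50 <- loadBuiltinScheme("blosum50", 13, 2)
STD20 <- alphabetSymbols(aaAlphabet())[1:20]

randSeq <- function(n) paste(sample(STD20, n, replace = TRUE), collapse = "")

# a small length-mixed database directory built from generated FASTA
makeTestDbDir <- function(nSeq = 60, meanLen = 200, maxLen = 2000, seed = 5) {
  td <- withr::local_tempdir(.local_envir = parent.frame())
  fa <- file.path(td, "in.fasta")
  writeFasta(genDistributedDb(nSeq, meanLen, maxLen, seed), fa)
  out <- file.path(td, "db")
  makeDb(fa, out)
  out
}
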