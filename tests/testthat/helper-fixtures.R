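# shared fixture cache: planted fixtures are deterministic per seed, so one
# copy serves every test file
.fx_cache <- new.env(parent = emptyenv())

get_fixture <- function(seed = 2) {
  key <- paste0("fx", seed)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- generate_fixture(seed)
  .fx_cache[[key]]
}

# a tiny hand-written PDB text block (three residues, one with altlocs)
TINY_PDB <- paste(
  "ATOM      1  N   ALA A  10      11.104   6.134  -6.504  1.00 10.00           N",
  "ATOM      2  CA  ALA A  10      11.639   6.071  -5.147  1.00 10.00           C",
  "ATOM      3  C   ALA A  10      12.697   7.152  -4.936  1.00 10.00           C",
  "ATOM      4  O   ALA A  10      13.560   7.342  -5.792  1.00 10.00           O",
  "ATOM      5  CB  ALA A  10      10.506   6.220  -4.128  1.00 10.00           C",
  "ATOM      6  N   SER A  11      12.639   7.861  -3.806  1.00 10.00           N",
  "ATOM      7  CA  SER A  11      13.600   8.924  -3.498  1.00 10.00           C",
  "ATOM      8  C   SER A  11      13.074  10.278  -3.967  1.00 10.00           C",
  "ATOM      9  O   SER A  11      11.875  10.530  -3.909  1.00 10.00           O",
  "ATOM     10  CB  SER A  11      13.864   8.974  -1.992  1.00 10.00           C",
  "ATOM     11  OG ASER A  11      14.966   9.823  -1.691  0.60 10.00           O",
  "ATOM     12  OG BSER A  11      12.741   9.473  -1.271  0.40 10.00           O",
  "ATOM     13  N   GLY A  12      13.978  11.157  -4.412  1.00 10.00           N",
  "ATOM     14  CA  GLY A  12      13.591  12.481  -4.894  1.00 10.00           C",
  "ATOM     15  C   GLY A  12      14.436  12.902  -6.089  1.00 10.00           C",
  "ATOM     16  O   GLY A  12      15.598  12.512  -6.207  1.00 10.00           O",
  "END",
  sep = "\n")
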