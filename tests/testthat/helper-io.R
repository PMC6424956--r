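# Fixture builders for IO tests (all fixtures are generated in code).

write_minimal_mzml <- function(mz, intensity, path) {
  enc <- function(x) {
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '  <cvList count="1"><cv id="MS" fullName="PSI-MS" ',
    'URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>\n',
    "  <fileDescription><fileContent>",
    '<cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum"/>',
    "</fileContent></fileDescription>\n",
    '  <run id="run1">\n    <spectrumList count="1">\n',
    '      <spectrum index="0" id="scan=1" defaultArrayLength="', length(mz), '">\n',
    '        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
    '        <binaryDataArrayList count="2">\n',
    '          <binaryDataArray encodedLength="', nchar(enc(mz)), '">\n',
    '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>\n',
    "            <binary>", enc(mz), "</binary>\n",
    "          </binaryDataArray>\n",
    '          <binaryDataArray encodedLength="', nchar(enc(intensity)), '">\n',
    '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>\n',
    "            <binary>", enc(intensity), "</binary>\n",
    "          </binaryDataArray>\n",
    "        </binaryDataArrayList>\n      </spectrum>\n",
    "    </spectrumList>\n  </run>\n</mzML>\n"
  )
  writeLines(xml, path)
  invisible(path)
}

# a small run configuration exercising the whole CLI quickly
demo_config <- function(dir, seed = 5) {
  cfg <- list(
    peptides = list(
      list(name = "demo", sequence = "AG", n_terminus = "acetyl_light", c_terminus = "amide")
    ),
    assay = list(
      v_donor_ul = 200, v_acceptor_ul = 800, time_s = 7200,
      area_cm2 = 1.12, c_donor0_um = 200
    ),
    sim = list(
      resolution = 2000, noise_sd = 0, baseline_level = 0,
      adduct_abundances = list(H = 1),
      intensity_scale = 100, step = 0.01
    ),
    quant = list(adducts = "H", correct_overlap = TRUE),
    seed = seed
  )
  path <- file.path(dir, "config.yaml")
  write_run_config(cfg, path)
  path
}
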