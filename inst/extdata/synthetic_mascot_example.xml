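<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic Mascot-style XML export (hand-built example, not real data):
     one protein hit with its sequence included and two peptide matches. -->
<mascot_search_results xmlns="http://www.matrixscience.com/xmlns/schema/mascot_search_results_2">
  <header>
    <NumQueries>2</NumQueries>
  </header>
  <hits>
    <hit number="1">
      <protein accession="SYNP01">
        <prot_desc>Synthetic example protein</prot_desc>
        <prot_seq>MAGKLSTRWQPGAVLDERTK</prot_seq>
        <peptide query="1" rank="1">
          <pep_seq>LSTR</pep_seq>
          <pep_start>5</pep_start>
          <pep_end>8</pep_end>
          <pep_score>45.2</pep_score>
        </peptide>
        <peptide query="2" rank="1">
          <pep_seq>GAVLDER</pep_seq>
          <pep_start>12</pep_start>
          <pep_end>18</pep_end>
          <pep_score>31.7</pep_score>
        </peptide>
      </protein>
    </hit>
  </hits>
</mascot_search_results>
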