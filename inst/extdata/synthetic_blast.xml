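<?xml version="1.0"?>
<!DOCTYPE BlastOutput PUBLIC "-//NCBI//NCBI BlastOutput/EN" "http://www.ncbi.nlm.nih.gov/dtd/NCBI_BlastOutput.dtd">
<!-- synthetic BLAST report for examples and tests: 5 hits, hand-written -->
<BlastOutput>
  <BlastOutput_program>blastp</BlastOutput_program>
  <BlastOutput_version>BLASTP 2.17.0+</BlastOutput_version>
  <BlastOutput_query-ID>Query_1</BlastOutput_query-ID>
  <BlastOutput_query-def>query_protein</BlastOutput_query-def>
  <BlastOutput_query-len>180</BlastOutput_query-len>
  <BlastOutput_iterations>
    <Iteration>
      <Iteration_iter-num>1</Iteration_iter-num>
      <Iteration_hits>
        <Hit>
          <Hit_num>1</Hit_num>
          <Hit_id>gi|1001</Hit_id>
          <Hit_def>hypothetical protein taxid=562</Hit_def>
          <Hit_accession>HP_0001</Hit_accession>
          <Hit_len>182</Hit_len>
          <Hit_hsps>
            <Hsp>
              <Hsp_num>1</Hsp_num>
              <Hsp_bit-score>310.5</Hsp_bit-score>
              <Hsp_evalue>1.4e-88</Hsp_evalue>
              <Hsp_identity>160</Hsp_identity>
              <Hsp_align-len>180</Hsp_align-len>
            </Hsp>
          </Hit_hsps>
        </Hit>
        <Hit>
          <Hit_num>2</Hit_num>
          <Hit_id>gi|1002</Hit_id>
          <Hit_def>two-domain protein taxid=1423</Hit_def>
          <Hit_accession>HP_0002</Hit_accession>
          <Hit_len>240</Hit_len>
          <Hit_hsps>
            <Hsp>
              <Hsp_num>1</Hsp_num>
              <Hsp_bit-score>80.0</Hsp_bit-score>
              <Hsp_evalue>2.0e-17</Hsp_evalue>
              <Hsp_identity>40</Hsp_identity>
              <Hsp_align-len>90</Hsp_align-len>
            </Hsp>
            <Hsp>
              <Hsp_num>2</Hsp_num>
              <Hsp_bit-score>120.0</Hsp_bit-score>
              <Hsp_evalue>5.0e-30</Hsp_evalue>
              <Hsp_identity>60</Hsp_identity>
              <Hsp_align-len>95</Hsp_align-len>
            </Hsp>
          </Hit_hsps>
        </Hit>
        <Hit>
          <Hit_num>3</Hit_num>
          <Hit_id>gi|1003</Hit_id>
          <Hit_def>ribosomal protein taxid=2188</Hit_def>
          <Hit_accession>HP_0003</Hit_accession>
          <Hit_len>175</Hit_len>
          <Hit_hsps>
            <Hsp>
              <Hsp_num>1</Hsp_num>
              <Hsp_bit-score>95.2</Hsp_bit-score>
              <Hsp_evalue>8.1e-22</Hsp_evalue>
              <Hsp_identity>52</Hsp_identity>
              <Hsp_align-len>160</Hsp_align-len>
            </Hsp>
          </Hit_hsps>
        </Hit>
        <Hit>
          <Hit_num>4</Hit_num>
          <Hit_id>gi|1004</Hit_id>
          <Hit_def>conserved protein taxid=3702</Hit_def>
          <Hit_accession>HP_0004</Hit_accession>
          <Hit_len>200</Hit_len>
          <Hit_hsps>
            <Hsp>
              <Hsp_num>1</Hsp_num>
              <Hsp_bit-score>62.8</Hsp_bit-score>
              <Hsp_evalue>3.7e-12</Hsp_evalue>
              <Hsp_identity>38</Hsp_identity>
              <Hsp_align-len>150</Hsp_align-len>
            </Hsp>
          </Hit_hsps>
        </Hit>
        <Hit>
          <Hit_num>5</Hit_num>
          <Hit_id>gi|1005</Hit_id>
          <Hit_def>weak match taxid=9606</Hit_def>
          <Hit_accession>HP_0005</Hit_accession>
          <Hit_len>95</Hit_len>
          <Hit_hsps>
            <Hsp>
              <Hsp_num>1</Hsp_num>
              <Hsp_bit-score>22.3</Hsp_bit-score>
              <Hsp_evalue>0.5</Hsp_evalue>
              <Hsp_identity>18</Hsp_identity>
              <Hsp_align-len>60</Hsp_align-len>
            </Hsp>
          </Hit_hsps>
        </Hit>
      </Iteration_hits>
    </Iteration>
  </BlastOutput_iterations>
</BlastOutput>
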