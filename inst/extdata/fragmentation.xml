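<?xml version="1.0" encoding="UTF-8"?>
<!-- Default fragmentation of the grading service: sequences of 2-4 atoms
     and bonds, formal charges and radical/lone-pair marks considered. -->
<fragmentation>
  <scheme>IAB</scheme>
  <minLength>2</minLength>
  <maxLength>4</maxLength>
  <formalCharge>true</formalCharge>
  <radicalsLonePairs>true</radicalsLonePairs>
</fragmentation>
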